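#' Skeleton objects
#'
#' A `skeleton3d` is a graph of 3D nodes with local radii: the
#' topology-preserving thin-line representation of a voxelized object. Per
#' connected component the edges form a tree, and one root per component is
#' recorded.
#'
#' @param nodes numeric matrix (n x 3, columns x, y, z, physical units).
#' @param radius numeric vector of local radii (> 0), one per node.
#' @param edges integer matrix (m x 2) of 1-based node index pairs.
#' @param roots integer vector, one node index per connected component.
#' @return a `skeleton3d`.
#' @export
skeleton3d <- function(nodes, radius, edges, roots = integer()) {
  nodes <- as.matrix(nodes)
  if (nrow(nodes) > 0L && ncol(nodes) != 3L) stop("nodes must be n x 3")
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) > 0L) {
    if (min(edges) < 1L || max(edges) > nrow(nodes))
      stop("edge index out of range")
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loop edge")
    if (anyDuplicated(edge_keys(edges))) stop("duplicate edge")
  }
  if (length(radius) != nrow(nodes)) stop("one radius per node required")
  if (nrow(nodes) > 0L && any(radius <= 0)) stop("radii must be positive")
  structure(list(nodes = nodes, radius = as.numeric(radius), edges = edges,
                 roots = as.integer(roots)),
            class = "skeleton3d")
}

#' @export
print.skeleton3d <- function(x, ...) {
  cat(sprintf("<skeleton3d> %d nodes, %d edges, %d component(s), length %.6g\n",
              nrow(x$nodes), nrow(x$edges), length(x$roots),
              skeleton_length(x)))
  invisible(x)
}

#' Total skeleton length
#'
#' Sum of Euclidean edge lengths in physical units; 0 for an empty skeleton.
#'
#' @param sk a [skeleton3d()].
#' @return scalar length.
#' @export
skeleton_length <- function(sk) {
  if (nrow(sk$edges) == 0L) return(0)
  d <- sk$nodes[sk$edges[, 1L], , drop = FALSE] -
    sk$nodes[sk$edges[, 2L], , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

#' @method tidy skeleton3d
#' @export
tidy.skeleton3d <- function(x, ...) {
  deg <- integer(nrow(x$nodes))
  if (nrow(x$edges) > 0L) {
    t1 <- table(factor(x$edges, levels = seq_len(nrow(x$nodes))))
    deg <- as.integer(t1)
  }
  xyz <- x$nodes
  rad <- x$radius
  root_flag <- seq_len(nrow(xyz)) %in% x$roots
  tibble::tibble(
    node = seq_len(nrow(xyz)),
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    radius = rad, degree = deg, is_root = root_flag
  )
}

#' @method glance skeleton3d
#' @export
glance.skeleton3d <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
    n_components = length(x$roots), total_length = skeleton_length(x),
    mean_radius = if (nrow(x$nodes)) mean(x$radius) else NA_real_
  )
}

# 26-connectivity neighbour offsets (half set; the graph is undirected)
half_offsets_26 <- function() {
  off <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  off <- off[!(off[, 1L] == 0 & off[, 2L] == 0 & off[, 3L] == 0), ]
  # keep one representative of each +/- pair
  keep <- off[, 3L] > 0 | (off[, 3L] == 0 & off[, 2L] > 0) |
    (off[, 3L] == 0 & off[, 2L] == 0 & off[, 1L] > 0)
  off[keep, , drop = FALSE]
}

#' Distance-to-boundary field
#'
#' Anisotropy-aware Euclidean distance from every foreground voxel to the
#' nearest background voxel (volume borders count as background). Doubles as
#' the local radius estimate of the skeletonizer.
#'
#' @param vol a [label_volume()]; any non-zero voxel is foreground.
#' @return numeric array, same dimensions as `vol$data`, physical units.
#' @export
distance_to_boundary <- function(vol) {
  mask <- vol$data != 0L
  dm <- dim(mask)
  padded <- array(FALSE, dm + 2L)
  padded[2:(dm[1L] + 1L), 2:(dm[2L] + 1L), 2:(dm[3L] + 1L)] <- mask
  d <- edt_cpp(padded, dim(padded), vol$spacing)
  d[2:(dm[1L] + 1L), 2:(dm[2L] + 1L), 2:(dm[3L] + 1L), drop = FALSE]
}

#' TEASAR-family skeletonization of a voxel volume
#'
#' Builds a centred tree skeleton per foreground component: (1) the Euclidean
#' distance-to-boundary field (DBF) is computed with anisotropic spacing;
#' (2) the component root is found by a two-pass farthest-point search over
#' the 26-connected voxel graph (edge weights = physical centre distances);
#' (3) shortest paths from the root to the farthest not-yet-covered voxel are
#' traced through a penalized metric that rewards staying on the DBF ridge
#' (per-voxel penalty proportional to `(1 - DBF/DBF_max)^penalty_exponent`),
#' each traced path invalidating all voxels within `scale * DBF + const` of
#' its nodes, until the whole component is covered; (4) traced paths are
#' merged into a tree and short leaf spurs (voxelization whiskers) are
#' pruned. Node radii are the DBF values. All tie-breaks use the lowest
#' linear voxel index, so the result is deterministic.
#'
#' @param vol a [label_volume()]; non-zero voxels are foreground.
#' @param scale invalidation radius factor (dimensionless, default 2).
#' @param const additive invalidation radius (physical units; default one
#'   mean voxel length).
#' @param penalty_exponent exponent of the centring penalty (default 4).
#' @param prune_spurs remove leaf branches shorter than
#'   `max(2 * DBF(junction), const)` (default `TRUE`).
#' @return a [skeleton3d()].
#' @export
skeletonize <- function(vol, scale = 2, const = NULL, penalty_exponent = 4,
                        prune_spurs = TRUE) {
  sp <- vol$spacing                       # (z, y, x)
  if (is.null(const)) const <- mean(sp)
  mask <- vol$data != 0L
  dm <- dim(mask)
  fg <- which(mask)                       # 1-based linear indices, sorted
  if (length(fg) == 0L)
    return(skeleton3d(matrix(0, 0L, 3L), numeric(), matrix(0L, 0L, 2L)))
  dbf <- distance_to_boundary(vol)
  # voxel (z,y,x) 0-based indices and physical (x,y,z) coordinates
  zi <- (fg - 1L) %% dm[1L]
  yi <- ((fg - 1L) %/% dm[1L]) %% dm[2L]
  xi <- (fg - 1L) %/% (dm[1L] * dm[2L])
  coords <- cbind(x = vol$origin[3L] + xi * sp[3L],
                  y = vol$origin[2L] + yi * sp[2L],
                  z = vol$origin[1L] + zi * sp[1L])
  node_of <- integer(prod(dm))
  node_of[fg] <- seq_along(fg)
  # undirected 26-connectivity edge list over foreground voxels
  offs <- half_offsets_26()
  efrom <- integer(0); eto <- integer(0); ew <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    dz <- offs[r, 1L]; dy <- offs[r, 2L]; dx <- offs[r, 3L]
    z2 <- zi + dz; y2 <- yi + dy; x2 <- xi + dx
    ok <- z2 >= 0L & z2 < dm[1L] & y2 >= 0L & y2 < dm[2L] &
      x2 >= 0L & x2 < dm[3L]
    lin2 <- z2[ok] + dm[1L] * (y2[ok] + dm[2L] * x2[ok]) + 1L
    nb <- node_of[lin2]
    src <- which(ok)[nb > 0L]
    nb <- nb[nb > 0L]
    efrom <- c(efrom, src); eto <- c(eto, nb)
    ew <- c(ew, rep(sqrt(sum((c(dz, dy, dx) * sp)^2)), length(nb)))
  }
  g <- igraph::make_graph(rbind(efrom, eto), n = length(fg), directed = FALSE)
  comps <- igraph::components(g)
  dbf_fg <- dbf[fg]
  # centring penalty per voxel, scaled to dominate path-length differences
  pen_scale <- 5000 * max(sp)
  all_nodes <- list(); all_edges <- list(); roots <- integer()
  node_offset <- 0L
  for (ci in seq_len(comps$no)) {
    members <- which(comps$membership == ci)   # ascending linear index order
    if (length(members) == 1L) {
      all_nodes[[length(all_nodes) + 1L]] <-
        cbind(coords[members, , drop = FALSE], dbf_fg[members])
      roots <- c(roots, node_offset + 1L)
      node_offset <- node_offset + 1L
      next
    }
    sub_sel <- efrom %in% members & eto %in% members
    sf <- match(efrom[sub_sel], members)
    st <- match(eto[sub_sel], members)
    sw <- ew[sub_sel]
    gs <- igraph::make_graph(rbind(sf, st), n = length(members),
                             directed = FALSE)
    dmax <- max(dbf_fg[members])
    pen <- pen_scale * (1 - dbf_fg[members] / dmax)^penalty_exponent
    wpen <- sw + 0.5 * (pen[sf] + pen[st])
    mcoords <- coords[members, , drop = FALSE]
    mdbf <- dbf_fg[members]
    # snap a path tip onto the medial axis: highest-DBF voxel within a local
    # ball (ties to the lowest linear index via member order)
    recenter <- function(i) {
      ctr <- mcoords[i, ]
      rad <- dmax + const
      cand <- which(sqrt(rowSums((mcoords -
                                    matrix(ctr, length(members), 3L,
                                           byrow = TRUE))^2)) <= rad)
      cand[which.max(mdbf[cand])]
    }
    # two-pass farthest point: seed = lowest linear index
    d_seed <- igraph::distances(gs, v = 1L, weights = sw)[1L, ]
    root_l <- recenter(which(d_seed == max(d_seed))[1L])
    d_root <- igraph::distances(gs, v = root_l, weights = sw)[1L, ]
    valid <- rep(TRUE, length(members))
    path_edges <- matrix(0L, 0L, 2L)
    path_nodes <- logical(length(members))
    path_nodes[root_l] <- TRUE
    wcur <- wpen
    edge_of <- function(a, b) igraph::get_edge_ids(gs, as.vector(rbind(a, b)))
    guard <- 0L
    while (any(valid)) {
      guard <- guard + 1L
      if (guard > 10000L) break
      cand <- which(valid)
      target_raw <- cand[which.max(d_root[cand])]  # ties: lowest index wins
      target <- recenter(target_raw)
      vp <- igraph::shortest_paths(gs, from = root_l, to = target,
                                   weights = wcur, output = "vpath")$vpath[[1L]]
      vp <- as.integer(vp)
      if (length(vp) >= 2L) {
        ep <- cbind(vp[-length(vp)], vp[-1L])
        path_edges <- rbind(path_edges, ep)
        # reuse traced paths: make their edges nearly free in the penalized
        # metric so later paths branch off the existing skeleton
        eid <- edge_of(ep[, 1L], ep[, 2L])
        wcur[eid] <- 1e-9 * sw[eid]
      }
      path_nodes[vp] <- TRUE
      # invalidate everything within scale * DBF + const of the path (the
      # raw farthest voxel counts as covered by the re-centred tip)
      rem <- which(valid)
      vp_cov <- unique(c(vp, target_raw))
      pc <- coords[members[vp_cov], , drop = FALSE]
      rr <- scale * dbf_fg[members[vp_cov]] + const
      for (k in seq_along(vp_cov)) {
        if (!length(rem)) break
        dd <- sqrt(rowSums((coords[members[rem], , drop = FALSE] -
                              matrix(pc[k, ], length(rem), 3L, byrow = TRUE))^2))
        rem <- rem[dd > rr[k]]
      }
      valid[] <- FALSE
      valid[rem] <- TRUE
    }
    keep <- which(path_nodes)
    remap <- integer(length(members)); remap[keep] <- seq_along(keep)
    uedges <- unique(cbind(pmin(path_edges[, 1L], path_edges[, 2L]),
                           pmax(path_edges[, 1L], path_edges[, 2L])))
    # safety: reduce the union of traced paths to a tree (minimum spanning
    # tree on physical edge lengths) in case path reuse left a cycle
    if (nrow(uedges) > 0L) {
      el <- sqrt(rowSums((coords[members[uedges[, 1L]], , drop = FALSE] -
                            coords[members[uedges[, 2L]], , drop = FALSE])^2))
      gt <- igraph::make_graph(rbind(remap[uedges[, 1L]], remap[uedges[, 2L]]),
                               n = length(keep), directed = FALSE)
      mst <- igraph::mst(gt, weights = el)
      uedges_t <- igraph::as_edgelist(mst, names = FALSE)
    } else uedges_t <- matrix(0L, 0L, 2L)
    all_nodes[[length(all_nodes) + 1L]] <-
      cbind(coords[members[keep], , drop = FALSE], dbf_fg[members[keep]])
    if (nrow(uedges_t) > 0L)
      all_edges[[length(all_edges) + 1L]] <- uedges_t + node_offset
    roots <- c(roots, node_offset + remap[root_l])
    node_offset <- node_offset + length(keep)
  }
  nodes_mat <- do.call(rbind, all_nodes)
  sk <- skeleton3d(nodes_mat[, 1:3, drop = FALSE], nodes_mat[, 4L],
                   if (length(all_edges)) do.call(rbind, all_edges)
                   else matrix(0L, 0L, 2L),
                   roots = roots)
  if (prune_spurs) sk <- prune_skeleton_spurs(sk, const = const)
  sk
}

# delete leaf branches shorter than max(2 * DBF at the junction, const)
prune_skeleton_spurs <- function(sk, const) {
  repeat {
    n <- nrow(sk$nodes)
    if (n == 0L || nrow(sk$edges) == 0L) return(sk)
    g <- igraph::make_graph(t(sk$edges), n = n, directed = FALSE)
    deg <- igraph::degree(g)
    removed <- rep(FALSE, n)
    changed <- FALSE
    for (leaf in which(deg == 1L)) {
      if (removed[leaf] || leaf %in% sk$roots) next
      # walk leaf -> first junction
      branch <- leaf
      prev <- 0L
      cur <- leaf
      len <- 0
      repeat {
        nbs <- setdiff(as.integer(igraph::neighbors(g, cur)), prev)
        if (length(nbs) == 0L) { branch <- NULL; break }
        nxt <- nbs[1L]
        len <- len + sqrt(sum((sk$nodes[cur, ] - sk$nodes[nxt, ])^2))
        if (deg[nxt] >= 3L) {
          junction <- nxt
          break
        }
        if (deg[nxt] == 1L) { branch <- NULL; break }   # pure path: keep
        branch <- c(branch, nxt)
        prev <- cur
        cur <- nxt
      }
      if (is.null(branch) || any(branch %in% sk$roots)) next
      if (len < max(2 * sk$radius[junction], const) &&
          !any(removed[branch])) {
        removed[branch] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) return(sk)
    keep <- which(!removed)
    remap <- integer(n); remap[keep] <- seq_along(keep)
    ek <- sk$edges[!removed[sk$edges[, 1L]] & !removed[sk$edges[, 2L]], ,
                   drop = FALSE]
    sk <- skeleton3d(sk$nodes[keep, , drop = FALSE], sk$radius[keep],
                     matrix(remap[ek], ncol = 2L),
                     roots = remap[sk$roots[!removed[sk$roots]]])
  }
}

#' Voxelize a watertight mesh
#'
#' A voxel is foreground iff its centre lies inside the mesh, decided by the
#' parity of ray crossings along +x; ray coordinates are nudged by a tiny
#' fraction of the bounding box so rays never graze edges or vertices. The
#' grid is the mesh bounding box padded by 2 voxels per side.
#'
#' @param mesh a watertight [tri_mesh()].
#' @param spacing physical voxel size `(z, y, x)` (scalar recycled).
#' @return a [label_volume()] with labels in {0, 1}.
#' @export
voxelize <- function(mesh, spacing) {
  if (!is_watertight(mesh))
    stop("open mesh: inside/outside is undefined, cannot voxelize")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) stop("spacing must be positive")
  sp <- as.numeric(spacing)               # (z, y, x)
  v <- mesh$vertices; f <- mesh$faces
  bbmin <- apply(v, 2L, min); bbmax <- apply(v, 2L, max)   # (x, y, z)
  sp_xyz <- rev(sp)
  n_xyz <- ceiling((bbmax - bbmin) / sp_xyz) + 4L
  orig_xyz <- bbmin - 1.5 * sp_xyz
  eps <- 1e-7 * max(bbox_diagonal(mesh), 1e-12)
  cx <- orig_xyz[1L] + (seq_len(n_xyz[1L]) - 1L) * sp_xyz[1L]
  cy <- orig_xyz[2L] + (seq_len(n_xyz[2L]) - 1L) * sp_xyz[2L] + eps
  cz <- orig_xyz[3L] + (seq_len(n_xyz[3L]) - 1L) * sp_xyz[3L] + eps * 0.618
  rays <- expand.grid(y = cy, z = cz)     # one +x ray per (y, z)
  np <- nrow(rays)
  hit_pt <- integer(0); hit_x <- numeric(0)
  A <- v[f[, 1L], , drop = FALSE]
  B <- v[f[, 2L], , drop = FALSE]
  C <- v[f[, 3L], , drop = FALSE]
  for (t in seq_len(nrow(f))) {
    a <- A[t, ]; b <- B[t, ]; cc <- C[t, ]
    det <- (b[2L] - a[2L]) * (cc[3L] - a[3L]) -
      (cc[2L] - a[2L]) * (b[3L] - a[3L])
    if (abs(det) < 1e-14) next            # triangle parallel to the ray
    py <- rays$y - a[2L]; pz <- rays$z - a[3L]
    wb <- (py * (cc[3L] - a[3L]) - (cc[2L] - a[2L]) * pz) / det
    wc <- ((b[2L] - a[2L]) * pz - py * (b[3L] - a[3L])) / det
    wa <- 1 - wb - wc
    inside <- wa > 0 & wb > 0 & wc > 0
    if (!any(inside)) next
    hit_pt <- c(hit_pt, which(inside))
    hit_x <- c(hit_x, wa[inside] * a[1L] + wb[inside] * b[1L] +
                 wc[inside] * cc[1L])
  }
  data <- array(0L, dim = c(n_xyz[3L], n_xyz[2L], n_xyz[1L]))  # (z, y, x)
  if (length(hit_pt)) {
    crossings <- split(hit_x, hit_pt)
    for (key in names(crossings)) {
      xs <- sort(crossings[[key]])
      if (length(xs) %% 2L != 0L) next    # grazing residue: skip the ray
      pid <- as.integer(key)
      iy <- (pid - 1L) %% n_xyz[2L] + 1L
      iz <- (pid - 1L) %/% n_xyz[2L] + 1L
      for (k in seq(1L, length(xs), by = 2L)) {
        sel <- cx > xs[k] & cx < xs[k + 1L]
        data[iz, iy, sel] <- 1L
      }
    }
  }
  label_volume(data, spacing = sp,
               origin = rev(orig_xyz))    # (z, y, x)
}
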