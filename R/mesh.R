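#' Triangle mesh objects
#'
#' A `tri_mesh` is the universal analysis substrate of the package: an indexed
#' triangle surface with vertices in physical units (conventionally
#' micrometres) and 0-based face indices stored internally as a 1-based R
#' integer matrix. All measurement functions ([surface_area()],
#' [enclosed_volume()], [slice_and_measure()], ...) operate on this type.
#'
#' @param vertices numeric matrix, one row per vertex, columns x, y, z.
#' @param faces integer matrix, one row per triangle, three 1-based vertex
#'   indices per row.
#' @param name text identifier carried into reports.
#' @param provenance source path or generator tag.
#' @param drop_degenerate drop faces with repeated vertex indices or zero
#'   area instead of failing; the number dropped is recorded in the
#'   `dropped_faces` attribute.
#' @return a `tri_mesh` object.
#' @export
tri_mesh <- function(vertices, faces, name = "mesh", provenance = NA_character_,
                     drop_degenerate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (nrow(faces) > 0L && ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face index out of range [1, ", nrow(vertices), "]")
  }
  dropped <- 0L
  if (drop_degenerate && nrow(faces) > 0L) {
    repeated <- faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
      faces[, 1L] == faces[, 3L]
    zero_area <- face_areas_raw(vertices, faces) <= 0
    bad <- repeated | zero_area
    dropped <- sum(bad)
    if (dropped > 0L) {
      faces <- faces[!bad, , drop = FALSE]
      message(sprintf("tri_mesh: dropped %d degenerate face(s)", dropped))
    }
  }
  dimnames(vertices) <- list(NULL, c("x", "y", "z"))
  dimnames(faces) <- NULL
  structure(
    list(name = name, vertices = vertices, faces = faces,
         provenance = provenance),
    dropped_faces = dropped,
    class = "tri_mesh"
  )
}

face_areas_raw <- function(v, f) {
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c <- v[f[, 3L], , drop = FALSE]
  cr <- cross3(b - a, c - a)
  0.5 * sqrt(rowSums(cr * cr))
}

cross3 <- function(u, v) {
  cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
        u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
        u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %s: %d vertices, %d faces\n",
              x$name, nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2L, range)
  cat(sprintf("  bbox x [%.4g, %.4g] y [%.4g, %.4g] z [%.4g, %.4g]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' @export
format.tri_mesh <- function(x, ...) {
  sprintf("<tri_mesh %s: %dv/%df>", x$name, nrow(x$vertices), nrow(x$faces))
}

bbox_diagonal <- function(mesh) {
  bb <- apply(mesh$vertices, 2L, range)
  sqrt(sum((bb[2L, ] - bb[1L, ])^2))
}

# Undirected edges of every face, as a 3F x 2 matrix (unsorted endpoints).
face_edges <- function(faces) {
  rbind(faces[, c(1L, 2L), drop = FALSE],
        faces[, c(2L, 3L), drop = FALSE],
        faces[, c(3L, 1L), drop = FALSE])
}

# Integer-free unique key per undirected edge (exact for < 2^26 vertices).
edge_keys <- function(edges) {
  lo <- pmin(edges[, 1L], edges[, 2L])
  hi <- pmax(edges[, 1L], edges[, 2L])
  as.numeric(lo) * 2^27 + as.numeric(hi)
}

#' Watertightness of a triangle mesh
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces and the two incident faces traverse it in opposite directions
#' (consistent winding). Watertightness is the precondition for a
#' well-defined enclosed volume.
#'
#' @param mesh a [tri_mesh()].
#' @return `TRUE`/`FALSE`; the number of boundary edges (edges not shared by
#'   exactly two faces) is attached as attribute `boundary_edges`.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(structure(FALSE, boundary_edges = 0L))
  ed <- face_edges(f)
  key <- edge_keys(ed)
  tab <- table(key)
  open_edges <- sum(tab != 2L)
  if (open_edges > 0L)
    return(structure(FALSE, boundary_edges = as.integer(open_edges)))
  # winding: a shared edge must appear once as (a,b) and once as (b,a)
  dir_key <- as.numeric(ed[, 1L]) * 2^27 + as.numeric(ed[, 2L])
  consistent <- !any(duplicated(dir_key))
  structure(consistent, boundary_edges = 0L)
}

#' Enforce consistent outward orientation
#'
#' Walks each edge-connected face component breadth-first, flipping faces so
#' winding is consistent across every shared edge, then flips whole closed
#' components so their enclosed volume is non-negative. Imported meshes pass
#' through this step so downstream signed integrals are meaningful.
#'
#' @param mesh a [tri_mesh()].
#' @return the re-oriented mesh.
#' @export
orient_mesh <- function(mesh) {
  f <- mesh$faces
  nf <- nrow(f)
  if (nf == 0L) return(mesh)
  ed <- face_edges(f)
  key <- edge_keys(ed)
  face_of_edge <- rep(seq_len(nf), 3L)
  by_key <- split(seq_along(key), key)
  # adjacency: faces sharing a manifold edge (exactly two incidences)
  adj <- vector("list", nf)
  pair_rows <- by_key[lengths(by_key) == 2L]
  if (length(pair_rows)) {
    m <- matrix(unlist(pair_rows, use.names = FALSE), ncol = 2L, byrow = TRUE)
    f1 <- face_of_edge[m[, 1L]]; f2 <- face_of_edge[m[, 2L]]
    adj_df <- rbind(cbind(f1, f2), cbind(f2, f1))
    adj <- split(adj_df[, 2L], factor(adj_df[, 1L], levels = seq_len(nf)))
  }
  flipped <- logical(nf)
  visited <- logical(nf)
  comp_id <- integer(nf)
  ncomp <- 0L
  # directed edge set per face, honouring the current flip state
  dir_edges <- function(i) {
    tri <- f[i, ]
    if (flipped[i]) tri <- tri[c(1L, 3L, 2L)]
    rbind(tri[c(1L, 2L)], tri[c(2L, 3L)], tri[c(3L, 1L)])
  }
  for (seed in seq_len(nf)) {
    if (visited[seed]) next
    ncomp <- ncomp + 1L
    queue <- integer(nf)
    queue[1L] <- seed
    tail <- 1L
    visited[seed] <- TRUE
    comp_id[seed] <- ncomp
    head <- 1L
    while (head <= tail) {
      cur <- queue[head]; head <- head + 1L
      de_cur <- dir_edges(cur)
      for (nb in adj[[cur]]) {
        if (visited[nb]) next
        de_nb <- dir_edges(nb)
        # winding is consistent iff the shared edge runs in opposite
        # directions in the two faces
        shared_same_dir <- FALSE
        for (r in 1:3) for (s in 1:3) {
          if (de_cur[r, 1L] == de_nb[s, 1L] && de_cur[r, 2L] == de_nb[s, 2L])
            shared_same_dir <- TRUE
        }
        if (shared_same_dir) flipped[nb] <- TRUE
        visited[nb] <- TRUE
        comp_id[nb] <- ncomp
        tail <- tail + 1L
        queue[tail] <- nb
      }
    }
  }
  if (any(flipped))
    f[flipped, ] <- f[flipped, c(1L, 3L, 2L), drop = FALSE]
  out <- mesh
  out$faces <- f
  # flip whole closed components with negative signed volume
  for (ci in seq_len(ncomp)) {
    rows <- which(comp_id == ci)
    sub <- out$faces[rows, , drop = FALSE]
    ed_s <- face_edges(sub)
    if (any(table(edge_keys(ed_s)) != 2L)) next  # open component: leave as-is
    sv <- signed_volume_raw(out$vertices, sub)
    if (sv < 0) out$faces[rows, ] <- sub[, c(1L, 3L, 2L), drop = FALSE]
  }
  out
}

signed_volume_raw <- function(v, f) {
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c <- v[f[, 3L], , drop = FALSE]
  sum(rowSums(a * cross3(b, c))) / 6
}
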