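# Shared fixtures (memoized: the heavier meshes/volumes are built once per
# test run) and independent oracles used to cross-check the implementation.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  hit <- .fixture_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- builder()
  assign(key, val, envir = .fixture_cache)
  val
}

fx_icosphere <- function(radius = 10, subdivisions = 4, center = c(0, 0, 0)) {
  fixture(sprintf("ico_%g_%d_%s", radius, subdivisions,
                  paste(center, collapse = "_")),
          function() make_icosphere(radius, subdivisions, center))
}

fx_cube <- function(edge = 1, center = c(0, 0, 0)) {
  fixture(sprintf("cube_%g_%s", edge, paste(center, collapse = "_")),
          function() make_cube(edge, center))
}

fx_cylinder <- function(radius = 3, height = 20, n_segments = 128) {
  fixture(sprintf("cyl_%g_%g_%d", radius, height, n_segments),
          function() make_cylinder(radius, height, n_segments))
}

fx_ball_volume <- function(radius = 20) {
  fixture(sprintf("ballvol_%g", radius), function() make_ball_volume(radius))
}

fx_tube_volume <- function() {
  fixture("tubevol", function() make_tube_volume(radius = 4, length_vox = 60))
}

fx_y_tube_volume <- function() {
  fixture("ytubevol", function() make_y_tube_volume(radius = 4,
                                                    arm_length = 25))
}

fx_ball_mesh <- function(radius = 20) {
  fixture(sprintf("ballmesh_%g", radius), function()
    labels_to_meshes(fx_ball_volume(radius)$volume)[["1"]])
}

# concatenate two meshes into one (disjoint union)
merge_meshes <- function(a, b, name = "merged") {
  tri_mesh(rbind(a$vertices, b$vertices),
           rbind(a$faces, b$faces + nrow(a$vertices)),
           name = name, drop_degenerate = FALSE)
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

transform_mesh <- function(mesh, rot = diag(3), shift = c(0, 0, 0)) {
  out <- mesh
  out$vertices <- mesh$vertices %*% t(rot) +
    matrix(shift, nrow(mesh$vertices), 3L, byrow = TRUE)
  out
}

# ---- independent oracles -------------------------------------------------

# Exhaustive relaxation (Bellman-Ford) over the mesh edge graph; shares no
# code with the package's shortest-path route.
bellman_ford_oracle <- function(mesh, src) {
  f <- mesh$faces
  ed <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  ek <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  ed <- ed[!duplicated(ek), , drop = FALSE]
  w <- sqrt(rowSums((mesh$vertices[ed[, 1], , drop = FALSE] -
                       mesh$vertices[ed[, 2], , drop = FALSE])^2))
  ef <- c(ed[, 1], ed[, 2]); et <- c(ed[, 2], ed[, 1]); ww <- c(w, w)
  d <- rep(Inf, nrow(mesh$vertices))
  d[src] <- 0
  repeat {
    cand <- d[ef] + ww
    upd <- tapply(cand, et, min)
    nd <- d
    idx <- as.integer(names(upd))
    nd[idx] <- pmin(nd[idx], upd)
    if (isTRUE(all.equal(nd, d, tolerance = 0)) || all(nd == d)) break
    d <- nd
  }
  d
}

# Scanline rasterization of a polygon set (even-odd rule) on an n x n grid:
# discrete area, centroid and second central moments -> ellipse axis lengths.
# Column runs are accumulated with closed-form arithmetic-series sums.
raster_moments_oracle <- function(loops, n = 2048) {
  allv <- do.call(rbind, loops)
  lo <- apply(allv, 2L, min); hi <- apply(allv, 2L, max)
  pad <- 0.01 * max(hi - lo)
  x0 <- lo[1L] - pad; x1 <- hi[1L] + pad
  y0 <- lo[2L] - pad; y1 <- hi[2L] + pad
  dx <- (x1 - x0) / n; dy <- (y1 - y0) / n
  xs <- x0 + (seq_len(n) - 0.5) * dx
  ys <- y0 + (seq_len(n) - 0.5) * dy
  segs <- do.call(rbind, lapply(loops, function(r) {
    rn <- rbind(r, r[1L, , drop = FALSE])
    cbind(rn[-nrow(rn), , drop = FALSE], rn[-1L, , drop = FALSE])
  }))
  cnt <- 0; Sx <- 0; Sy <- 0; Sxx <- 0; Syy <- 0; Sxy <- 0
  for (j in seq_len(n)) {
    y <- ys[j]
    cr <- (segs[, 2L] > y) != (segs[, 4L] > y)
    if (!any(cr)) next
    xi <- segs[cr, 1L] + (y - segs[cr, 2L]) /
      (segs[cr, 4L] - segs[cr, 2L]) * (segs[cr, 3L] - segs[cr, 1L])
    xi <- sort(xi)
    for (k in seq(1L, length(xi) - 1L, by = 2L)) {
      i_lo <- findInterval(xi[k], xs) + 1L
      i_hi <- findInterval(xi[k + 1L], xs)
      m <- i_hi - i_lo + 1L
      if (m <= 0L) next
      a0 <- xs[i_lo]
      sx <- m * (a0 + xs[i_hi]) / 2
      sxx <- m * a0^2 + 2 * a0 * dx * (m - 1) * m / 2 +
        dx^2 * (m - 1) * m * (2 * m - 1) / 6
      cnt <- cnt + m
      Sx <- Sx + sx
      Sxx <- Sxx + sxx
      Sy <- Sy + m * y
      Syy <- Syy + m * y^2
      Sxy <- Sxy + sx * y
    }
  }
  cxm <- Sx / cnt; cym <- Sy / cnt
  mxx <- Sxx / cnt - cxm^2
  myy <- Syy / cnt - cym^2
  mxy <- Sxy / cnt - cxm * cym
  ev <- eigen(matrix(c(mxx, mxy, mxy, myy), 2L), symmetric = TRUE,
              only.values = TRUE)$values
  list(area = cnt * dx * dy, centroid = c(cxm, cym),
       minor_axis_length = 4 * sqrt(max(ev[2L], 0)),
       major_axis_length = 4 * sqrt(ev[1L]))
}

# Independent area-uniform surface sampler for the angular oracle: cumulative
# area inversion + rejection barycentric draw (different algorithm from the
# package's reflected-barycentric sampler).
oracle_surface_samples <- function(mesh, n, seed) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  cc <- v[f[, 3L], , drop = FALSE]
  cr <- cbind((b - a)[, 2] * (cc - a)[, 3] - (b - a)[, 3] * (cc - a)[, 2],
              (b - a)[, 3] * (cc - a)[, 1] - (b - a)[, 1] * (cc - a)[, 3],
              (b - a)[, 1] * (cc - a)[, 2] - (b - a)[, 2] * (cc - a)[, 1])
  areas <- 0.5 * sqrt(rowSums(cr^2))
  cum <- cumsum(areas) / sum(areas)
  set.seed(seed)
  tri <- findInterval(stats::runif(n), cum) + 1L
  u <- stats::runif(n); w <- stats::runif(n)
  bad <- u + w > 1
  while (any(bad)) {             # rejection: resample outside the triangle
    u[bad] <- stats::runif(sum(bad)); w[bad] <- stats::runif(sum(bad))
    bad <- u + w > 1
  }
  a[tri, , drop = FALSE] * (1 - u - w) + b[tri, , drop = FALSE] * u +
    cc[tri, , drop = FALSE] * w
}

oracle_angles <- function(samples, reference, fixed) {
  u <- (fixed - reference) / sqrt(sum((fixed - reference)^2))
  vs <- samples - matrix(reference, nrow(samples), 3L, byrow = TRUE)
  acos(pmin(1, pmax(-1, (vs %*% u) / sqrt(rowSums(vs^2)))))
}
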