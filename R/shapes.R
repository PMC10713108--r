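#' Synthetic test shapes with known analytic properties
#'
#' The fixture factory standing in for microscopy data: watertight meshes
#' (icosphere, cube, cylinder, torus) and label volumes (ball, tube, Y-tube,
#' multi-label) whose surface area, volume, axes, endpoints and voxel counts
#' are known in closed form. Every generator returns the object together with
#' an `analytic` record; all generators are deterministic for a given seed.
#'
#' @param kind shape kind; one of `"icosphere"`, `"cube"`, `"cylinder"`,
#'   `"torus"`.
#' @param ... kind-specific parameters, see the individual generators.
#' @return list with elements `mesh` (a [tri_mesh()]) and `analytic` (named
#'   list of closed-form properties and the refinement-dependent tolerance).
#' @export
make_mesh <- function(kind = c("icosphere", "cube", "cylinder", "torus"), ...) {
  kind <- match.arg(kind)
  switch(kind,
         icosphere = make_icosphere(...),
         cube = make_cube(...),
         cylinder = make_cylinder(...),
         torus = make_torus(...))
}

#' @rdname make_mesh
#' @param radius sphere radius (physical units).
#' @param subdivisions icosahedron subdivision level (>= 0).
#' @param center sphere centre.
#' @export
make_icosphere <- function(radius = 1, subdivisions = 3L, center = c(0, 0, 0)) {
  if (radius <= 0) stop("radius must be positive")
  if (subdivisions < 0L) stop("subdivisions must be >= 0")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  v <- v / sqrt(rowSums(v^2)[1L])
  for (s in seq_len(subdivisions)) {
    edge_mid <- new.env(hash = TRUE)
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(i, j) {
      key <- paste0(min(i, j), "_", max(i, j))
      hit <- edge_mid[[key]]
      if (!is.null(hit)) return(hit)
      m <- v[i, ] + v[j, ]
      m <- m / sqrt(sum(m^2))
      newv[[length(newv) + 1L]] <<- m
      id <- nv + length(newv)
      edge_mid[[key]] <- id
      id
    }
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1L]; b <- f[t, 2L]; cc <- f[t, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[(t - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                           c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    v <- v / sqrt(rowSums(v^2))          # project back onto the sphere
    f <- newf
  }
  v <- v * radius
  v <- sweep(v, 2L, center, "+")
  mesh <- tri_mesh(v, f, name = sprintf("icosphere_r%g_s%d", radius,
                                        subdivisions),
                   provenance = "generator:icosphere")
  if (signed_volume_raw(mesh$vertices, mesh$faces) < 0)
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  # inscribed polyhedron: measured deficit shrinks ~4x per subdivision
  tol <- c(0.40, 0.12, 0.035, 0.012, 0.01, 0.01)[min(subdivisions, 5L) + 1L]
  list(mesh = mesh,
       analytic = list(kind = "icosphere", radius = radius, center = center,
                       area = 4 * pi * radius^2,
                       volume = 4 / 3 * pi * radius^3,
                       tolerance = tol))
}

#' @rdname make_mesh
#' @param edge cube edge length.
#' @export
make_cube <- function(edge = 1, center = c(0, 0, 0)) {
  h <- edge / 2
  v <- as.matrix(expand.grid(x = c(-h, h), y = c(-h, h), z = c(-h, h)))
  v <- sweep(v, 2L, center, "+")
  # 12 outward-wound triangles
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z-
    c(5, 6, 7), c(6, 8, 7),   # z+
    c(1, 2, 5), c(2, 6, 5),   # y-
    c(3, 7, 4), c(4, 7, 8),   # y+
    c(1, 5, 3), c(3, 5, 7),   # x-
    c(2, 4, 6), c(4, 8, 6)    # x+
  )
  mesh <- tri_mesh(v, f, name = sprintf("cube_e%g", edge),
                   provenance = "generator:cube")
  if (signed_volume_raw(mesh$vertices, mesh$faces) < 0)
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  list(mesh = mesh,
       analytic = list(kind = "cube", edge = edge, center = center,
                       area = 6 * edge^2, volume = edge^3, tolerance = 0))
}

#' @rdname make_mesh
#' @param height cylinder height (axis along z).
#' @param n_segments circumferential resolution.
#' @export
make_cylinder <- function(radius = 1, height = 2, n_segments = 64L,
                          center = c(0, 0, 0)) {
  ang <- 2 * pi * (seq_len(n_segments) - 1L) / n_segments
  ring <- cbind(radius * cos(ang), radius * sin(ang))
  zlo <- -height / 2; zhi <- height / 2
  v <- rbind(cbind(ring, zlo), cbind(ring, zhi),
             c(0, 0, zlo), c(0, 0, zhi))
  clo <- 2L * n_segments + 1L; chi <- 2L * n_segments + 2L
  nxt <- c(seq_len(n_segments)[-1L], 1L)
  f <- rbind(
    cbind(seq_len(n_segments), nxt, n_segments + nxt),                 # side
    cbind(seq_len(n_segments), n_segments + nxt, n_segments + seq_len(n_segments)),
    cbind(clo, nxt, seq_len(n_segments)),                              # bottom
    cbind(chi, n_segments + seq_len(n_segments), n_segments + nxt)     # top
  )
  v <- sweep(v, 2L, center, "+")
  mesh <- tri_mesh(v, f, name = sprintf("cylinder_r%g_h%g", radius, height),
                   provenance = "generator:cylinder")
  if (signed_volume_raw(mesh$vertices, mesh$faces) < 0)
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  list(mesh = mesh,
       analytic = list(kind = "cylinder", radius = radius, height = height,
                       center = center, axis = c(0, 0, 1),
                       area = 2 * pi * radius * height + 2 * pi * radius^2,
                       volume = pi * radius^2 * height,
                       tolerance = pi^2 / (2 * n_segments^2) * 6))
}

#' @rdname make_mesh
#' @param ring_radius distance from torus centre to tube centre (R).
#' @param tube_radius tube radius (r < R); torus axis along z.
#' @param n_ring,n_tube resolution of the two parameter circles.
#' @export
make_torus <- function(ring_radius = 10, tube_radius = 2, n_ring = 96L,
                       n_tube = 32L, center = c(0, 0, 0)) {
  if (tube_radius >= ring_radius) stop("tube_radius must be < ring_radius")
  iu <- rep(seq_len(n_ring), each = n_tube)
  iv <- rep(seq_len(n_tube), times = n_ring)
  uu <- 2 * pi * (iu - 1L) / n_ring
  vv <- 2 * pi * (iv - 1L) / n_tube
  v <- cbind((ring_radius + tube_radius * cos(vv)) * cos(uu),
             (ring_radius + tube_radius * cos(vv)) * sin(uu),
             tube_radius * sin(vv))
  v <- sweep(v, 2L, center, "+")
  vid <- function(i, j) ((i - 1L) %% n_ring) * n_tube + ((j - 1L) %% n_tube) + 1L
  i <- rep(seq_len(n_ring), each = n_tube)
  j <- rep(seq_len(n_tube), times = n_ring)
  f <- rbind(cbind(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L)),
             cbind(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L)))
  mesh <- tri_mesh(v, f, name = sprintf("torus_R%g_r%g", ring_radius,
                                        tube_radius),
                   provenance = "generator:torus")
  if (signed_volume_raw(mesh$vertices, mesh$faces) < 0)
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  list(mesh = mesh,
       analytic = list(kind = "torus", ring_radius = ring_radius,
                       tube_radius = tube_radius, center = center,
                       axis = c(0, 0, 1),
                       area = 4 * pi^2 * ring_radius * tube_radius,
                       volume = 2 * pi^2 * ring_radius * tube_radius^2,
                       tolerance = 0.02))
}

#' Synthetic label volumes
#'
#' @param kind one of `"ball"`, `"tube"`, `"y_tube"`, `"multilabel"` (the
#'   `_volume` suffix is also accepted).
#' @param ... kind-specific parameters, see the individual generators.
#' @return list with elements `volume` (a [label_volume()]) and `analytic`.
#' @export
make_volume <- function(kind = c("ball", "tube", "y_tube", "multilabel",
                                 "ball_volume", "tube_volume",
                                 "y_tube_volume", "multilabel_volume"), ...) {
  kind <- sub("_volume$", "", match.arg(kind))
  switch(kind,
         ball = make_ball_volume(...),
         tube = make_tube_volume(...),
         y_tube = make_y_tube_volume(...),
         multilabel = make_multilabel_volume(...))
}

#' @rdname make_volume
#' @param radius ball radius in physical units.
#' @param spacing voxel size `(z, y, x)`.
#' @export
make_ball_volume <- function(radius = 20, spacing = c(1, 1, 1)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  n <- ceiling(2 * radius / rev(spacing)) + 5L    # (x, y, z) counts
  n_zyx <- rev(n)
  cen <- (n_zyx - 1) / 2 * spacing
  zc <- (seq_len(n_zyx[1L]) - 1L) * spacing[1L] - cen[1L]
  yc <- (seq_len(n_zyx[2L]) - 1L) * spacing[2L] - cen[2L]
  xc <- (seq_len(n_zyx[3L]) - 1L) * spacing[3L] - cen[3L]
  d2 <- outer(outer(zc^2, yc^2, "+"), xc^2, "+")
  data <- array(0L, n_zyx)
  data[d2 <= radius^2] <- 1L
  vol <- label_volume(data, spacing = spacing)
  list(volume = vol,
       analytic = list(kind = "ball", radius = radius,
                       center_zyx = cen,
                       voxel_count = sum(data),
                       volume = 4 / 3 * pi * radius^3))
}

#' @rdname make_volume
#' @param length_vox tube length along z, in voxels.
#' @export
make_tube_volume <- function(radius = 4, length_vox = 60,
                             spacing = c(1, 1, 1)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  ny <- 2L * ceiling(radius / spacing[2L]) + 5L
  nx <- 2L * ceiling(radius / spacing[3L]) + 5L
  nz <- length_vox + 4L
  cy <- (ny - 1) / 2 * spacing[2L]
  cx <- (nx - 1) / 2 * spacing[3L]
  yc <- (seq_len(ny) - 1L) * spacing[2L] - cy
  xc <- (seq_len(nx) - 1L) * spacing[3L] - cx
  disk <- outer(yc^2, xc^2, "+") <= radius^2
  data <- array(0L, c(nz, ny, nx))
  z_in <- 3:(length_vox + 2L)             # 2 empty slices at each end
  for (iz in z_in) {
    sl <- data[iz, , ]
    sl[disk] <- 1L
    data[iz, , ] <- sl
  }
  vol <- label_volume(data, spacing = spacing)
  z0 <- (min(z_in) - 1L) * spacing[1L]
  z1 <- (max(z_in) - 1L) * spacing[1L]
  list(volume = vol,
       analytic = list(kind = "tube", radius = radius,
                       length = z1 - z0,
                       axis_xy = c(cx, cy),        # physical (x, y) of axis
                       z_range = c(z0, z1),
                       voxel_count = sum(data),
                       volume = pi * radius^2 * (z1 - z0)))
}

#' @rdname make_volume
#' @param arm_length arm length in physical units.
#' @export
make_y_tube_volume <- function(radius = 4, arm_length = 25,
                               spacing = c(1, 1, 1)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  pad <- radius + 3
  ext <- arm_length + pad
  # junction at the origin, arms in the (z, y) plane
  dirs <- rbind(c(-1, 0, 0),                        # down (z, y, x)
                c(1 / sqrt(2),  1 / sqrt(2), 0),    # up-right
                c(1 / sqrt(2), -1 / sqrt(2), 0))    # up-left
  ends <- dirs * arm_length
  zr <- range(c(0, ends[, 1L])); yr <- range(c(0, ends[, 2L]))
  lo <- c(zr[1L] - pad, yr[1L] - pad, -pad)
  hi <- c(zr[2L] + pad, yr[2L] + pad, pad)
  nzyx <- ceiling((hi - lo) / spacing) + 1L
  zc <- lo[1L] + (seq_len(nzyx[1L]) - 1L) * spacing[1L]
  yc <- lo[2L] + (seq_len(nzyx[2L]) - 1L) * spacing[2L]
  xc <- lo[3L] + (seq_len(nzyx[3L]) - 1L) * spacing[3L]
  pts <- as.matrix(expand.grid(z = zc, y = yc, x = xc))
  inside <- rep(FALSE, nrow(pts))
  for (k in 1:3) {
    b <- ends[k, ]
    t <- pmin(pmax((pts %*% b) / sum(b^2), 0), 1)
    dd <- pts - t %*% t(b)
    inside <- inside | rowSums(dd^2) <= radius^2
  }
  data <- array(0L, nzyx)
  data[inside] <- 1L
  vol <- label_volume(data, spacing = spacing, origin = lo)
  # endpoints / junction in physical (x, y, z)
  to_xyz <- function(p) c(p[3L], p[2L], p[1L])
  list(volume = vol,
       analytic = list(kind = "y_tube", radius = radius,
                       arm_length = arm_length,
                       junction = to_xyz(c(0, 0, 0)),
                       endpoints = t(apply(ends, 1L, to_xyz)),
                       voxel_count = sum(data)))
}

#' @rdname make_volume
#' @param radii radii of the disjoint balls (labels 1, 2, ...).
#' @param seed placement seed.
#' @export
make_multilabel_volume <- function(radii = c(6, 5, 4), spacing = c(1, 1, 1),
                                   seed = 0L) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  n_lab <- length(radii)
  # deterministic jittered placement along the x axis, guaranteed disjoint
  gaps <- withr_seed(seed, stats::runif(n_lab, 2, 4))
  cx <- cumsum(c(radii[1L] + 3, utils::head(radii, -1L) + radii[-1L] + gaps[-1L]))
  maxr <- max(radii)
  ny <- 2L * ceiling(maxr) + 7L
  nzc <- ny
  nx <- ceiling(max(cx) + maxr + 3)
  nzyx <- c(nzc, ny, nx)
  zc <- seq_len(nzc) - 1; yc <- seq_len(ny) - 1; xc <- seq_len(nx) - 1
  cz <- (nzc - 1) / 2; cyy <- (ny - 1) / 2
  data <- array(0L, nzyx)
  counts <- integer(n_lab)
  for (k in seq_len(n_lab)) {
    d2 <- outer(outer((zc - cz)^2, (yc - cyy)^2, "+"), (xc - cx[k])^2, "+")
    sel <- d2 <= radii[k]^2
    counts[k] <- sum(sel)
    data[sel] <- k
  }
  vol <- label_volume(data, spacing = spacing)
  list(volume = vol,
       analytic = list(kind = "multilabel", radii = radii,
                       centers_x = cx, voxel_counts = counts))
}
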