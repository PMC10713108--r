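#' Center lines
#'
#' An ordered 3D polyline along which slicing planes are placed. Stored with
#' the cumulative arc length per point.
#'
#' @param points numeric matrix (n >= 2 rows, columns x, y, z); consecutive
#'   points must be distinct.
#' @return a `center_line`.
#' @export
center_line <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("center-line points must have 3 columns")
  if (nrow(points) < 2L) stop("a center line needs at least 2 points")
  seg <- diff(points)
  seg_len <- sqrt(rowSums(seg^2))
  if (any(seg_len == 0)) stop("consecutive center-line points must be distinct")
  structure(list(points = points, arc_length = c(0, cumsum(seg_len))),
            class = "center_line")
}

#' @export
print.center_line <- function(x, ...) {
  cat(sprintf("<center_line> %d points, length %.6g\n",
              nrow(x$points), max(x$arc_length)))
  invisible(x)
}

#' Read a center line from a plain-text point list
#'
#' One `x y z` triple per line, whitespace separated; blank lines and lines
#' starting with `#` are ignored.
#'
#' @param path text file path.
#' @return a [center_line()].
#' @export
read_centerline <- function(path) {
  if (!file.exists(path)) stop("center-line file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  pts <- do.call(rbind, lapply(lines, function(l)
    as.numeric(strsplit(l, "[ \t,]+")[[1L]][1:3])))
  if (any(is.na(pts))) stop("malformed center-line point list: ", path)
  center_line(pts)
}

#' Build a center line from points or from a mesh's principal axis
#'
#' `method = "explicit"` passes a point list through unchanged. `method =
#' "principal-axis"` fits a straight line through the vertex centroid along
#' the dominant principal direction of the vertex cloud, clips it to the
#' extent of the vertex projections and discretizes it into `n_points`
#' equally spaced stations. If the top two covariance eigenvalues differ by
#' less than 10% the cloud has no clear elongation; the dominant axis is
#' still used but a low-anisotropy warning is raised.
#'
#' @param source numeric point matrix (explicit) or a [tri_mesh()]
#'   (principal-axis).
#' @param method `"explicit"` or `"principal-axis"`.
#' @param n_points stations for the discretized principal-axis line.
#' @return a [center_line()].
#' @export
build_centerline <- function(source, method = c("explicit", "principal-axis"),
                             n_points = 50L) {
  method <- match.arg(method)
  if (method == "explicit") {
    if (inherits(source, "center_line")) return(source)
    return(center_line(source))
  }
  if (!inherits(source, "tri_mesh"))
    stop("principal-axis method needs a tri_mesh")
  v <- source$vertices
  if (nrow(v) < 3L) stop("need at least 3 vertices for a principal axis")
  cen <- colMeans(v)
  cv <- stats::cov(v)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[1L] <= .Machine$double.eps * max(1, sum(diag(cv))))
    stop("degenerate vertex cloud: no principal direction")
  if (eg$values[2L] > 0 &&
      (eg$values[1L] - eg$values[2L]) / eg$values[1L] < 0.10)
    warning("low anisotropy: top two principal components within 10%; axis is ill-determined")
  dir <- eg$vectors[, 1L]
  proj <- drop((v - matrix(cen, nrow(v), 3L, byrow = TRUE)) %*% dir)
  if (max(proj) - min(proj) <= 0) stop("degenerate vertex cloud: zero extent")
  t_st <- seq(min(proj), max(proj), length.out = max(2L, n_points))
  center_line(matrix(cen, length(t_st), 3L, byrow = TRUE) + outer(t_st, dir))
}

# linear interpolation of a point at arc-length station s
centerline_point_at <- function(cl, s) {
  al <- cl$arc_length
  s <- min(max(s, 0), max(al))
  i <- findInterval(s, al, rightmost.closed = TRUE)
  i <- min(i, length(al) - 1L)
  f <- (s - al[i]) / (al[i + 1L] - al[i])
  cl$points[i, ] + f * (cl$points[i + 1L, ] - cl$points[i, ])
}

# unit tangent at a station: direction of the containing segment; at interior
# polyline vertices the mean of the adjacent segment directions
centerline_tangent_at <- function(cl, s) {
  al <- cl$arc_length
  seg <- diff(cl$points)
  segd <- seg / sqrt(rowSums(seg^2))
  n <- nrow(segd)
  eps <- 1e-12 * max(al)
  at_vertex <- which(abs(al - s) <= eps)
  if (length(at_vertex) && at_vertex[1L] > 1L && at_vertex[1L] <= n) {
    d <- segd[at_vertex[1L] - 1L, ] + segd[at_vertex[1L], ]
  } else {
    i <- findInterval(min(max(s, 0), max(al)), al, rightmost.closed = TRUE)
    i <- min(max(i, 1L), n)
    d <- segd[i, ]
  }
  d / sqrt(sum(d^2))
}

#' Place slicing planes along a center line
#'
#' Stations are equally spaced in arc length over `[0, L]` with the end
#' stations inset by half a step, which avoids the tangent ambiguity at the
#' polyline ends: `n` sections sit at `(i - 1/2) L / n`. With `step` given,
#' the count is `floor(L / step)` (at least one). The plane normal is the
#' local unit tangent.
#'
#' @param cl a [center_line()].
#' @param n_sections number of planes (mutually exclusive with `step`).
#' @param step arc-length spacing; if larger than the line, a single mid-line
#'   plane is placed with a warning.
#' @return tibble with columns `station`, `origin_x/y/z`, `normal_x/y/z`.
#' @export
place_planes <- function(cl, n_sections = NULL, step = NULL) {
  L <- max(cl$arc_length)
  if (is.null(n_sections) == is.null(step))
    stop("give exactly one of n_sections or step")
  if (!is.null(step)) {
    if (step <= 0) stop("step must be positive")
    if (step > L) {
      warning("step exceeds center-line length; placing a single mid-line plane")
      n_sections <- 1L
      step <- L
    } else n_sections <- max(1L, floor(L / step))
  } else {
    if (n_sections < 1L) stop("n_sections must be >= 1")
    step <- L / n_sections
  }
  stations <- (seq_len(n_sections) - 0.5) * step
  origins <- t(vapply(stations, function(s) centerline_point_at(cl, s),
                      numeric(3)))
  normals <- t(vapply(stations, function(s) centerline_tangent_at(cl, s),
                      numeric(3)))
  tibble::tibble(
    station = stations,
    origin_x = origins[, 1L], origin_y = origins[, 2L], origin_z = origins[, 3L],
    normal_x = normals[, 1L], normal_y = normals[, 2L], normal_z = normals[, 3L]
  )
}

#' A single slicing plane
#'
#' @param origin point on the plane.
#' @param normal plane normal (normalized internally).
#' @param station arc-length coordinate carried into reports.
#' @return a `section_plane`.
#' @export
section_plane <- function(origin, normal, station = NA_real_) {
  nrm <- sqrt(sum(normal^2))
  if (nrm == 0) stop("zero-length plane normal")
  structure(list(origin = as.numeric(origin), normal = as.numeric(normal) / nrm,
                 station = station), class = "section_plane")
}

# orthonormal in-plane basis (u, v) completing the normal to a right-handed
# frame
plane_basis <- function(normal) {
  n <- normal / sqrt(sum(normal^2))
  a <- if (abs(n[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2L] * u[3L] - n[3L] * u[2L],   # v = n x u, so (u, v, n) is
         n[3L] * u[1L] - n[1L] * u[3L],   # right handed
         n[1L] * u[2L] - n[2L] * u[1L])
  list(u = u, v = v)
}

#' Intersect a mesh with a plane
#'
#' Every triangle crossing the plane contributes one segment; segments are
#' chained into closed loops through the mesh edges they cross (the crossing
#' point on a shared edge is computed once, so chaining is exact), then
#' projected into the plane's orthonormal (u, v) frame. Loops are classified
#' outer/hole by containment parity and normalized: outer rings
#' counter-clockwise, holes clockwise. Vertices lying exactly on the plane
#' are nudged by 1e-9 of the bounding-box diagonal along the normal first,
#' removing in-plane triangle degeneracies.
#'
#' @param mesh a [tri_mesh()].
#' @param plane a [section_plane()] (or a 1-row tibble from [place_planes()]).
#' @return a `section_polygon`: list with `loops` (list of n x 2 matrices),
#'   `is_hole` (logical), `open_chains` (count of discarded open chains),
#'   `plane`, and the (u, v) frame. Empty intersection gives zero loops.
#' @export
plane_mesh_intersection <- function(mesh, plane) {
  plane <- as_section_plane(plane)
  v <- mesh$vertices
  f <- mesh$faces
  n <- plane$normal
  d <- drop(v %*% n) - sum(plane$origin * n)
  eps <- 1e-9 * max(bbox_diagonal(mesh), 1e-12)
  d[d == 0] <- eps                      # nudge on-plane vertices
  basis <- plane_basis(n)
  empty <- structure(list(loops = list(), is_hole = logical(), open_chains = 0L,
                          plane = plane, u = basis$u, v = basis$v),
                     class = "section_polygon")
  if (nrow(f) == 0L) return(empty)
  s1 <- d[f[, 1L]]; s2 <- d[f[, 2L]]; s3 <- d[f[, 3L]]
  crossing <- (pmin(s1, s2, s3) < 0) & (pmax(s1, s2, s3) > 0)
  if (!any(crossing)) return(empty)
  fc <- f[crossing, , drop = FALSE]
  # per crossing face, the two edges with a sign change
  seg_a <- integer(0); seg_b <- integer(0)       # edge keys per segment
  edge_key <- function(i, j) edge_keys(cbind(i, j))
  e12 <- sign(d[fc[, 1L]]) != sign(d[fc[, 2L]])
  e23 <- sign(d[fc[, 2L]]) != sign(d[fc[, 3L]])
  e31 <- sign(d[fc[, 3L]]) != sign(d[fc[, 1L]])
  k12 <- edge_key(fc[, 1L], fc[, 2L])
  k23 <- edge_key(fc[, 2L], fc[, 3L])
  k31 <- edge_key(fc[, 3L], fc[, 1L])
  keys <- rbind(ifelse(e12, k12, NA), ifelse(e23, k23, NA),
                ifelse(e31, k31, NA))
  seg_keys <- apply(keys, 2L, function(col) col[!is.na(col)][1:2])
  seg_a <- seg_keys[1L, ]; seg_b <- seg_keys[2L, ]
  # crossing point per unique cut edge
  all_keys <- unique(c(seg_a, seg_b))
  lo <- floor(all_keys / 2^27); hi <- all_keys - lo * 2^27
  t_cross <- d[lo] / (d[lo] - d[hi])
  pts <- v[lo, , drop = FALSE] +
    (v[hi, , drop = FALSE] - v[lo, , drop = FALSE]) * t_cross
  a_id <- match(seg_a, all_keys); b_id <- match(seg_b, all_keys)
  # chain segments into loops: walk node -> unused incident segment -> ...
  nseg <- length(a_id)
  inc <- split(rep(seq_len(nseg), 2L), c(a_id, b_id))
  inc_of <- vector("list", length(all_keys))
  inc_of[as.integer(names(inc))] <- inc
  used <- logical(nseg)
  loops <- list(); open_chains <- 0L
  for (s0 in seq_len(nseg)) {
    if (used[s0]) next
    used[s0] <- TRUE
    start <- a_id[s0]
    cur <- b_id[s0]
    ring <- c(start, cur)
    closed <- FALSE
    repeat {
      nxt_seg <- NA_integer_
      for (sg in inc_of[[cur]]) if (!used[sg]) { nxt_seg <- sg; break }
      if (is.na(nxt_seg)) break
      used[nxt_seg] <- TRUE
      cur <- if (a_id[nxt_seg] == cur) b_id[nxt_seg] else a_id[nxt_seg]
      if (cur == start) { closed <- TRUE; break }
      ring <- c(ring, cur)
    }
    if (closed && length(ring) >= 3L) {
      loops[[length(loops) + 1L]] <- ring
    } else open_chains <- open_chains + 1L
  }
  if (open_chains > 0L)
    warning(open_chains, " open section chain(s) discarded (mesh boundary cut)")
  if (length(loops) == 0L) return(empty)
  # project to (u, v)
  origin <- plane$origin
  uv <- cbind(drop((pts - matrix(origin, nrow(pts), 3L, byrow = TRUE)) %*% basis$u),
              drop((pts - matrix(origin, nrow(pts), 3L, byrow = TRUE)) %*% basis$v))
  rings2d <- lapply(loops, function(r) uv[r, , drop = FALSE])
  # drop zero-area slivers
  areas <- vapply(rings2d, ring_signed_area, numeric(1))
  keep <- abs(areas) > 0
  rings2d <- rings2d[keep]; areas <- areas[keep]
  if (length(rings2d) == 0L) return(empty)
  # outer/hole by containment parity, winding normalized
  is_hole <- logical(length(rings2d))
  for (i in seq_along(rings2d)) {
    p0 <- rings2d[[i]][1L, ]
    depth <- 0L
    for (j in seq_along(rings2d)) {
      if (i == j) next
      if (point_in_ring(p0, rings2d[[j]])) depth <- depth + 1L
    }
    is_hole[i] <- depth %% 2L == 1L
    want_ccw <- !is_hole[i]
    if ((areas[i] > 0) != want_ccw) rings2d[[i]] <- rings2d[[i]][nrow(rings2d[[i]]):1L, , drop = FALSE]
  }
  structure(list(loops = rings2d, is_hole = is_hole, open_chains = open_chains,
                 plane = plane, u = basis$u, v = basis$v),
            class = "section_polygon")
}

as_section_plane <- function(x) {
  if (inherits(x, "section_plane")) return(x)
  if (is.data.frame(x) && nrow(x) == 1L)
    return(section_plane(c(x$origin_x, x$origin_y, x$origin_z),
                         c(x$normal_x, x$normal_y, x$normal_z),
                         station = if ("station" %in% names(x)) x$station else NA_real_))
  stop("cannot interpret plane")
}

ring_signed_area <- function(r) {
  x <- r[, 1L]; y <- r[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

ring_perimeter <- function(r) {
  dx <- diff(rbind(r, r[1L, , drop = FALSE]))
  sum(sqrt(rowSums(dx^2)))
}

# even-odd ray casting (robust enough for chained crossing points)
point_in_ring <- function(p, r) {
  x <- r[, 1L]; y <- r[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  crosses <- ((y > p[2L]) != (yn > p[2L]))
  if (!any(crosses)) return(FALSE)
  xi <- x[crosses] + (p[2L] - y[crosses]) / (yn[crosses] - y[crosses]) *
    (xn[crosses] - x[crosses])
  sum(xi > p[1L]) %% 2L == 1L
}
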