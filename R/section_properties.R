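#' Construct a section polygon from explicit rings
#'
#' Mostly useful for testing and for importing 2D outlines: rings are
#' classified outer/hole by containment parity and their winding is
#' normalized (outer counter-clockwise, holes clockwise), exactly as
#' [plane_mesh_intersection()] does for mesh cuts.
#'
#' @param loops list of n x 2 numeric matrices (closed rings, last vertex
#'   implicitly connected to the first).
#' @return a `section_polygon`.
#' @export
section_polygon <- function(loops) {
  loops <- lapply(loops, function(r) {
    r <- as.matrix(r); storage.mode(r) <- "double"; r
  })
  if (any(vapply(loops, nrow, integer(1)) < 3L))
    stop("each ring needs at least 3 vertices")
  areas <- vapply(loops, ring_signed_area, numeric(1))
  if (any(areas == 0)) stop("ring with zero signed area")
  is_hole <- logical(length(loops))
  for (i in seq_along(loops)) {
    p0 <- loops[[i]][1L, ]
    depth <- sum(vapply(seq_along(loops), function(j)
      j != i && point_in_ring(p0, loops[[j]]), logical(1)))
    is_hole[i] <- depth %% 2L == 1L
    if ((areas[i] > 0) == is_hole[i])
      loops[[i]] <- loops[[i]][nrow(loops[[i]]):1L, , drop = FALSE]
  }
  structure(list(loops = loops, is_hole = is_hole, open_chains = 0L,
                 plane = NULL, u = c(1, 0, 0), v = c(0, 1, 0)),
            class = "section_polygon")
}

#' @export
print.section_polygon <- function(x, ...) {
  cat(sprintf("<section_polygon> %d ring(s) (%d hole(s)), %d open chain(s)\n",
              length(x$loops), sum(x$is_hole), x$open_chains))
  invisible(x)
}

# area-weighted second central moments of the polygonal region (holes carry
# negative signed area and subtract automatically)
polygon_moments <- function(loops) {
  A <- 0; Sx <- 0; Sy <- 0; Sxx <- 0; Syy <- 0; Sxy <- 0
  for (r in loops) {
    x <- r[, 1L]; y <- r[, 2L]
    xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
    cr <- x * yn - xn * y
    A <- A + sum(cr) / 2
    Sx <- Sx + sum((x + xn) * cr) / 6
    Sy <- Sy + sum((y + yn) * cr) / 6
    Sxx <- Sxx + sum((x^2 + x * xn + xn^2) * cr) / 12
    Syy <- Syy + sum((y^2 + y * yn + yn^2) * cr) / 12
    Sxy <- Sxy + sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  }
  list(area = A, cx = Sx / A, cy = Sy / A,
       # normalized central second moments
       mxx = Sxx / A - (Sx / A)^2,
       myy = Syy / A - (Sy / A)^2,
       mxy = Sxy / A - (Sx / A) * (Sy / A))
}

#' Geometric properties of one cross-section
#'
#' Computes the nine per-section descriptors: area (outer rings minus holes,
#' shoelace), perimeter (all ring boundaries including holes), convex area
#' and convex perimeter (hull over all ring vertices), equivalent diameter
#' `sqrt(4 area / pi)`, convexity in terms of area (`area / convex_area`),
#' convexity in terms of perimeter (`convex_perimeter / perimeter`, hull over
#' total so it stays <= 1), and minor/major axis lengths of the ellipse with
#' the same normalized second central moments as the region (the convention
#' of standard 2D region-properties tools: axis length = 4 sqrt(eigenvalue)).
#'
#' @param poly a `section_polygon` with at least one closed outer loop.
#' @return one-row tibble with the nine properties.
#' @export
section_properties <- function(poly) {
  if (!inherits(poly, "section_polygon")) stop("need a section_polygon")
  if (length(poly$loops) == 0L || all(poly$is_hole))
    stop("no closed outer loop in section")
  mom <- polygon_moments(poly$loops)
  area <- mom$area
  if (area <= 0) stop("degenerate section: non-positive area after hole subtraction")
  perimeter <- sum(vapply(poly$loops, ring_perimeter, numeric(1)))
  allv <- do.call(rbind, poly$loops)
  hull <- allv[grDevices::chull(allv), , drop = FALSE]
  convex_area <- abs(ring_signed_area(hull))
  convex_perimeter <- ring_perimeter(hull)
  ev <- eigen(matrix(c(mom$mxx, mom$mxy, mom$mxy, mom$myy), 2L, 2L),
              symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  tibble::tibble(
    area = area,
    perimeter = perimeter,
    convex_area = convex_area,
    convex_perimeter = convex_perimeter,
    equivalent_diameter = sqrt(4 * area / pi),
    convexity_area = area / convex_area,
    convexity_perimeter = convex_perimeter / perimeter,
    minor_axis_length = 4 * sqrt(ev[2L]),
    major_axis_length = 4 * sqrt(ev[1L])
  )
}

section_na_row <- function() {
  tibble::tibble(
    area = NA_real_, perimeter = NA_real_, convex_area = NA_real_,
    convex_perimeter = NA_real_, equivalent_diameter = NA_real_,
    convexity_area = NA_real_, convexity_perimeter = NA_real_,
    minor_axis_length = NA_real_, major_axis_length = NA_real_
  )
}

#' Slice a mesh along a center line and measure every section
#'
#' Places `n_sections` planes perpendicular to the center line (see
#' [place_planes()]), intersects the mesh with each and computes the nine
#' section properties. Planes that miss the object produce a row of `NA`s; if
#' every plane misses, the center line does not pass through the object and
#' an error is raised.
#'
#' @param mesh a [tri_mesh()].
#' @param cl a [center_line()] (or point matrix).
#' @param n_sections number of planes.
#' @param step alternative to `n_sections`: arc-length spacing.
#' @return tibble `station` + the nine property columns, one row per plane,
#'   class `section_table`.
#' @export
slice_and_measure <- function(mesh, cl, n_sections = NULL, step = NULL) {
  cl <- build_centerline(cl, method = "explicit")
  planes <- place_planes(cl, n_sections = n_sections, step = step)
  rows <- vector("list", nrow(planes))
  any_hit <- FALSE
  for (i in seq_len(nrow(planes))) {
    poly <- plane_mesh_intersection(mesh, planes[i, ])
    props <- if (length(poly$loops) == 0L || all(poly$is_hole))
      section_na_row()
    else {
      any_hit <- TRUE
      section_properties(poly)
    }
    rows[[i]] <- tibble::tibble(station = planes$station[i], props)
  }
  if (!any_hit) stop("center line misses object: every section is empty")
  out <- do.call(rbind, rows)
  class(out) <- c("section_table", class(out))
  out
}

#' @method autoplot section_table
#' @export
autoplot.section_table <- function(object, property = "area", ...) {
  df <- as.data.frame(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$station,
                                   y = .data[[property]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "arc-length station", y = property,
                  title = "cross-section profile")
}
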