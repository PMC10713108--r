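test_that("center lines carry arc length and validate input", {
  cl <- center_line(rbind(c(0, 0, 0), c(0, 0, 10)))
  expect_equal(cl$arc_length, c(0, 10))
  expect_error(center_line(rbind(c(0, 0, 0), c(0, 0, 0))), "distinct")
  expect_error(center_line(matrix(0, 1, 3)), "at least 2")
})

test_that("principal-axis center lines recover a cylinder's axis", {
  cy <- fx_cylinder(3, 20, 64)$mesh
  cl <- build_centerline(cy, method = "principal-axis", n_points = 10)
  d <- cl$points[nrow(cl$points), ] - cl$points[1L, ]
  d <- d / sqrt(sum(d^2))
  angle <- acos(min(1, abs(sum(d * c(0, 0, 1)))))
  expect_lt(angle, 1 * pi / 180)
  expect_lt(abs(max(cl$arc_length) - 20) / 20, 0.05)

  # a sphere has no preferred axis: low-anisotropy warning
  expect_warning(build_centerline(fx_icosphere(5, 2)$mesh,
                                  method = "principal-axis"),
                 "anisotropy")
})

test_that("plane placement is arc-length uniform with half-step end insets", {
  cl <- center_line(rbind(c(0, 0, 0), c(0, 0, 10)))
  pl <- place_planes(cl, n_sections = 3)
  expect_equal(pl$station, c(1, 3, 5) * 10 / 6)
  expect_true(all(abs(pl$normal_z - 1) < 1e-12))

  # floor-based count for step spacing: count x spacing <= L
  pl2 <- place_planes(cl, step = 4)
  expect_equal(nrow(pl2), 2L)
  expect_equal(diff(pl2$station), 4)
  expect_lte(nrow(pl2) * 4, 10)

  expect_warning(pl3 <- place_planes(cl, step = 99), "single")
  expect_equal(nrow(pl3), 1L)

  # corner normal = normalized mean of adjacent segment directions
  corner <- center_line(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))
  tangent <- morphmesh:::centerline_tangent_at(corner, 1)
  expect_equal(tangent, c(1, 1, 0) / sqrt(2), tolerance = 1e-12)
})

test_that("plane-mesh intersection produces the expected loops", {
  cb <- fx_cube(1, c(0.5, 0.5, 0.5))$mesh
  sec <- plane_mesh_intersection(cb, section_plane(c(0.5, 0.5, 0.5), c(0, 0, 1)))
  expect_length(sec$loops, 1L)
  props <- section_properties(sec)
  expect_equal(props$area, 1, tolerance = 1e-9)
  expect_equal(props$perimeter, 4, tolerance = 1e-9)

  expect_length(plane_mesh_intersection(
    cb, section_plane(c(0, 0, 2), c(0, 0, 1)))$loops, 0L)

  # sphere cut at z = 6: circle of radius sqrt(100 - 36) = 8
  ic <- fx_icosphere(10, 4)$mesh
  s3 <- plane_mesh_intersection(ic, section_plane(c(0, 0, 6), c(0, 0, 1)))
  expect_length(s3$loops, 1L)
  ring <- s3$loops[[1L]]
  r <- sqrt(rowSums(scale(ring, scale = FALSE)^2))
  expect_true(all(abs(r - 8) / 8 < 0.01))

  # axial torus cut: two disjoint tube circles, both outer
  to <- fixture("torus", function() make_torus(10, 2))$mesh
  s4 <- plane_mesh_intersection(to, section_plane(c(0, 0, 0), c(0, 1, 0)))
  expect_length(s4$loops, 2L)
  expect_false(any(s4$is_hole))

  # z-normal torus cut through the middle: annulus = outer ring + hole
  s5 <- plane_mesh_intersection(to, section_plane(c(0, 0, 0), c(0, 0, 1)))
  expect_length(s5$loops, 2L)
  expect_equal(sum(s5$is_hole), 1L)
})

test_that("section properties match hand computations", {
  sq <- section_polygon(list(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))))
  p <- section_properties(sq)
  expect_equal(p$area, 1)
  expect_equal(p$perimeter, 4)
  expect_equal(p$convex_area, 1)
  expect_equal(p$convex_perimeter, 4)
  expect_equal(p$equivalent_diameter, 2 / sqrt(pi))
  expect_equal(p$convexity_area, 1)
  expect_equal(p$convexity_perimeter, 1)
  # moments-equivalent ellipse of the unit square: both axes 2/sqrt(3)
  expect_equal(p$major_axis_length, 2 / sqrt(3), tolerance = 1e-12)
  expect_lt(abs(p$major_axis_length - p$minor_axis_length), 1e-9)

  # L-shape: 2x2 minus 1x1 corner; hull is a pentagon of area 3.5
  L <- section_polygon(list(cbind(c(0, 2, 2, 1, 1, 0), c(0, 0, 1, 1, 2, 2))))
  pL <- section_properties(L)
  expect_equal(pL$area, 3)
  expect_equal(pL$perimeter, 8)
  expect_equal(pL$convex_area, 3.5)
  expect_equal(pL$convexity_area, 3 / 3.5)

  # 2x2 square with centered 1x1 hole: hole boundary counts in the perimeter
  holed <- section_polygon(list(
    cbind(c(0, 2, 2, 0), c(0, 0, 2, 2)),
    cbind(c(0.5, 1.5, 1.5, 0.5), c(0.5, 0.5, 1.5, 1.5))
  ))
  ph <- section_properties(holed)
  expect_equal(ph$area, 3)
  expect_equal(ph$perimeter, 12)
  expect_equal(ph$convex_area, 4)
  expect_equal(ph$convexity_perimeter, 8 / 12)

  # regular 256-gon ~ circle of radius 5
  ang <- 2 * pi * (0:255) / 256
  gon <- section_polygon(list(cbind(5 * cos(ang), 5 * sin(ang))))
  pg <- section_properties(gon)
  expect_lt(abs(pg$major_axis_length - 10) / 10, 0.005)
  expect_lt(abs(pg$minor_axis_length - 10) / 10, 0.005)
  expect_gt(pg$convexity_area, 0.999)
  expect_gt(pg$convexity_perimeter, 0.999)
})

test_that("axis lengths agree with the rasterized moment oracle", {
  shapes <- list(
    square = list(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))),
    L = list(cbind(c(0, 2, 2, 1, 1, 0), c(0, 0, 1, 1, 2, 2))),
    holed = list(cbind(c(0, 2, 2, 0), c(0, 0, 2, 2)),
                 cbind(c(0.5, 1.5, 1.5, 0.5), c(0.5, 0.5, 1.5, 1.5))),
    gon = list(cbind(5 * cos(2 * pi * (0:255) / 256),
                     5 * sin(2 * pi * (0:255) / 256)))
  )
  for (nm in names(shapes)) {
    p <- section_properties(section_polygon(shapes[[nm]]))
    o <- raster_moments_oracle(shapes[[nm]], n = 2048)
    expect_lt(abs(p$area - o$area) / o$area, 0.01, label = nm)
    expect_lt(abs(p$major_axis_length - o$major_axis_length) /
                o$major_axis_length, 0.01, label = nm)
    expect_lt(abs(p$minor_axis_length - o$minor_axis_length) /
                o$minor_axis_length, 0.01, label = nm)
  }
})

test_that("section property invariants hold on convex shapes and under rigid motion", {
  set.seed(21)
  meshes <- list(fx_cube(2, c(0, 0, 0))$mesh, fx_icosphere(5, 3)$mesh,
                 fx_cylinder(3, 10, 64)$mesh)
  for (m in meshes) {
    for (k in 1:4) {
      nrm <- stats::rnorm(3); nrm <- nrm / sqrt(sum(nrm^2))
      orig <- colMeans(m$vertices) + stats::runif(3, -0.5, 0.5)
      sec <- plane_mesh_intersection(m, section_plane(orig, nrm))
      if (length(sec$loops) == 0L) next
      p <- section_properties(sec)
      expect_gte(p$convexity_area, 0.99)
      expect_lte(p$convexity_area, 1 + 1e-12)
      expect_gte(p$convexity_perimeter, 0.99)
      expect_lte(p$convexity_perimeter, 1 + 1e-12)
      expect_lte(p$area, p$convex_area * (1 + 1e-12))
      expect_gte(p$perimeter, p$convex_perimeter * (1 - 1e-12))
      expect_lte(p$minor_axis_length, p$major_axis_length)
      expect_equal(p$equivalent_diameter, sqrt(4 * p$area / pi))
    }
  }
  # rotating mesh + center line together leaves section properties unchanged
  cy <- fx_cylinder(3, 20, 64)$mesh
  cl_pts <- rbind(c(0, 0, -10), c(0, 0, 10))
  base <- slice_and_measure(cy, cl_pts, n_sections = 7)
  set.seed(5)
  rot <- random_rotation(); shift <- stats::rnorm(3, 0, 20)
  cy2 <- transform_mesh(cy, rot, shift)
  cl2 <- cl_pts %*% t(rot) + matrix(shift, 2, 3, byrow = TRUE)
  moved <- slice_and_measure(cy2, cl2, n_sections = 7)
  for (col in setdiff(names(base), "station"))
    expect_lt(max(abs(moved[[col]] - base[[col]]) / pmax(base[[col]], 1e-12)),
              1e-6)
})

test_that("slice_and_measure reproduces analytic section profiles", {
  cy <- fx_cylinder(3, 20, 128)$mesh
  tab <- slice_and_measure(cy, rbind(c(0, 0, -10), c(0, 0, 10)),
                           n_sections = 5)
  expect_s3_class(tab, "section_table")
  expect_equal(nrow(tab), 5L)
  expect_true(all(abs(tab$equivalent_diameter - 6) / 6 < 0.02))

  ic <- fx_icosphere(10, 4)$mesh
  tb <- slice_and_measure(ic, rbind(c(0, 0, -10), c(0, 0, 10)),
                          n_sections = 20)
  z <- tb$station - 10
  analytic <- pi * (100 - z^2)
  expect_true(all(abs(tb$area - analytic) / analytic < 0.02))

  expect_error(
    slice_and_measure(cy, rbind(c(0, 0, 50), c(0, 0, 60)), n_sections = 3),
    "misses object")
})

test_that("Cavalieri integration of section areas reproduces the volume", {
  for (fx in list(fx_cylinder(3, 20, 128), fx_icosphere(10, 4))) {
    m <- fx$mesh
    bb <- range(m$vertices[, 3L])
    tab <- slice_and_measure(m, rbind(c(0, 0, bb[1L]), c(0, 0, bb[2L])),
                             n_sections = 200)
    step <- (bb[2L] - bb[1L]) / 200
    integ <- sum(tab$area, na.rm = TRUE) * step
    vol <- enclosed_volume(m)
    expect_lt(abs(integ - vol) / vol, 0.02)
  }
})
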