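test_that("surface area matches closed forms", {
  tri <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                  matrix(c(1, 2, 3), 1L))
  expect_equal(surface_area(tri), 0.5)
  expect_equal(surface_area(fx_cube()$mesh), 6, tolerance = 1e-14)
  ic <- fx_icosphere(10, 4)
  expect_lt(abs(surface_area(ic$mesh) - ic$analytic$area) / ic$analytic$area,
            0.01)
  # inscribed polyhedron area is strictly below the sphere area
  expect_lt(surface_area(ic$mesh), ic$analytic$area)
})

test_that("enclosed volume matches closed forms and is translation invariant", {
  cb <- fx_cube()$mesh
  expect_equal(enclosed_volume(cb), 1, tolerance = 1e-14)
  moved <- transform_mesh(cb, shift = c(100, -50, 7))
  expect_equal(enclosed_volume(moved), 1, tolerance = 1e-9)
  ic <- fx_icosphere(10, 4)
  vol <- enclosed_volume(ic$mesh)
  expect_lt(abs(vol - ic$analytic$volume) / ic$analytic$volume, 0.01)
  expect_lt(vol, ic$analytic$volume)
})

test_that("open meshes refuse a volume unless forced", {
  open_mesh <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                        matrix(c(1, 2, 3), 1L))
  expect_false(as.logical(is_watertight(open_mesh)))
  expect_error(enclosed_volume(open_mesh), "open mesh")
  expect_warning(v <- enclosed_volume(open_mesh, force = TRUE), "open mesh")
  expect_gte(v, 0)
})

test_that("connected components partition faces and conserve area", {
  c1 <- fx_cube()$mesh
  c2 <- transform_mesh(fx_cube()$mesh, shift = c(5, 0, 0))
  two <- merge_meshes(c1, c2)
  comps <- connected_components(two)
  expect_length(comps, 2L)
  expect_equal(vapply(comps, function(m) nrow(m$faces), integer(1)),
               c(12L, 12L))

  tri <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                  matrix(c(1, 2, 3), 1L))
  expect_length(connected_components(tri), 1L)

  set.seed(11)
  blob <- fx_icosphere(1, 1)$mesh
  m <- blob
  for (k in 1:4)
    m <- merge_meshes(m, transform_mesh(blob, shift = stats::runif(3, 5, 50) * k))
  comps5 <- connected_components(m)
  expect_length(comps5, 5L)
  expect_equal(sum(vapply(comps5, surface_area, numeric(1))),
               surface_area(m), tolerance = 1e-12)
})

test_that("measure() batches per-mesh results without aborting on open meshes", {
  open_mesh <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                        matrix(c(1, 2, 3), 1L), name = "open")
  tab <- measure(list(fx_cube()$mesh, fx_icosphere(2, 2)$mesh, open_mesh))
  expect_s3_class(tab, "tbl_df")
  expect_equal(nrow(tab), 3L)
  expect_false(any(is.na(tab$volume[1:2])))
  expect_true(is.na(tab$volume[3L]))
  expect_match(tab$note[3L], "open_mesh")
  # batching is a no-op: totals equal single-mesh calls
  metrics <- vapply(list(fx_cube()$mesh, fx_icosphere(2, 2)$mesh),
                    surface_area, numeric(1))
  expect_equal(tab$surface_area[1:2], metrics)
})

test_that("area and volume obey the scale law and rigid invariance", {
  ic <- fx_icosphere(2, 2)$mesh
  a0 <- surface_area(ic); v0 <- enclosed_volume(ic)
  for (s in c(0.5, 2, 10)) {
    scaled <- ic
    scaled$vertices <- ic$vertices * s
    expect_equal(surface_area(scaled), a0 * s^2, tolerance = 1e-12)
    expect_equal(enclosed_volume(scaled), v0 * s^3, tolerance = 1e-12)
  }
  set.seed(7)
  for (k in 1:5) {
    rigid <- transform_mesh(ic, rot = random_rotation(),
                            shift = stats::rnorm(3, 0, 50))
    expect_lt(abs(surface_area(rigid) - a0) / a0, 1e-9)
    expect_lt(abs(enclosed_volume(rigid) - v0) / v0, 1e-9)
  }
})

test_that("flipping all windings negates the raw signed volume", {
  cb <- fx_cube()$mesh
  raw <- morphmesh:::signed_volume_raw(cb$vertices, cb$faces)
  flipped <- cb$faces[, c(1L, 3L, 2L)]
  expect_equal(morphmesh:::signed_volume_raw(cb$vertices, flipped), -raw)
  # public API still reports the non-negative value
  fm <- cb; fm$faces <- flipped
  expect_equal(enclosed_volume(fm), abs(raw))
})

test_that("glance and tidy summarize meshes as tibbles", {
  g <- glance(fx_cube()$mesh)
  expect_equal(g$surface_area, 6)
  expect_equal(g$volume, 1)
  td <- tidy(fx_cube()$mesh)
  expect_equal(nrow(td), 8L)
  expect_named(td, c("vertex", "x", "y", "z"))
})
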