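test_that("voxelization fills the expected voxel counts", {
  cb <- fx_cube(1, c(0, 0, 0))$mesh
  v <- voxelize(cb, 0.25)
  expect_lt(abs(sum(v$data) - 64) / 64, 0.10)

  ic <- fx_icosphere(10, 3)$mesh
  vs <- voxelize(ic, 1)
  expect_lt(abs(sum(vs$data) - 4188) / 4188, 0.05)

  # voxelize -> mesh -> volume round trip at spacing = r/10
  m2 <- labels_to_meshes(vs)[["1"]]
  expect_lt(abs(enclosed_volume(m2) - enclosed_volume(ic)) /
              enclosed_volume(ic), 0.10)

  open_mesh <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                        matrix(c(1, 2, 3), 1L))
  expect_error(voxelize(open_mesh, 0.5), "open mesh")
})

test_that("a straight tube skeletonizes to a centred single path", {
  tv <- fx_tube_volume()
  sk <- fixture("tube_sk", function() skeletonize(tv$volume))
  td <- tidy(sk)
  # single path: two endpoints, no branching
  expect_equal(sum(td$degree == 1L), 2L)
  expect_equal(sum(td$degree > 2L), 0L)
  expect_length(sk$roots, 1L)
  ax <- tv$analytic$axis_xy
  d_axis <- sqrt((td$x - ax[1L])^2 + (td$y - ax[2L])^2)
  expect_lte(mean(d_axis), 1)
  expect_lte(max(d_axis), 2)
  expect_lt(abs(skeleton_length(sk) - tv$analytic$length) /
              tv$analytic$length, 0.15)
})

test_that("skeleton nodes stay inside the originating mask", {
  tv <- fx_tube_volume()
  sk <- fixture("tube_sk", function() skeletonize(tv$volume))
  sp <- tv$volume$spacing
  dm <- dim(tv$volume$data)
  for (i in seq_len(nrow(sk$nodes))) {
    ix <- round(sk$nodes[i, 1L] / sp[3L]) + 1L
    iy <- round(sk$nodes[i, 2L] / sp[2L]) + 1L
    iz <- round(sk$nodes[i, 3L] / sp[1L]) + 1L
    expect_equal(tv$volume$data[iz, iy, ix], 1L)
  }
  expect_true(all(sk$radius > 0))
})

test_that("a ball collapses to a near-degenerate skeleton", {
  bv <- fx_ball_volume(15)
  sk <- skeletonize(bv$volume)
  expect_length(sk$roots, 1L)
  expect_lt(skeleton_length(sk), 30)     # below the ball diameter
})

test_that("a Y junction keeps exactly three leaves and one branch node", {
  yv <- fx_y_tube_volume()
  sk <- skeletonize(yv$volume)
  td <- tidy(sk)
  expect_equal(sum(td$degree == 1L), 3L)
  expect_equal(sum(td$degree == 3L), 1L)
  expect_equal(sum(td$degree > 3L), 0L)
  expect_length(sk$roots, 1L)
  # per-component tree: |E| = |V| - components
  expect_equal(nrow(sk$edges), nrow(sk$nodes) - 1L)
})

test_that("skeletonization is deterministic and monotone in scale", {
  tv <- fx_tube_volume()
  sk1 <- skeletonize(tv$volume)
  sk2 <- skeletonize(tv$volume)
  expect_identical(sk1, sk2)
  counts <- vapply(c(1, 2, 4), function(s)
    nrow(skeletonize(tv$volume, scale = s)$nodes), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("degenerate volumes produce degenerate skeletons", {
  empty <- label_volume(array(0L, c(3, 3, 3)))
  sk0 <- skeletonize(empty)
  expect_equal(nrow(sk0$nodes), 0L)
  expect_equal(skeleton_length(sk0), 0)

  one <- array(0L, c(3, 3, 3)); one[2, 2, 2] <- 1L
  sk1 <- skeletonize(label_volume(one))
  expect_equal(nrow(sk1$nodes), 1L)
  expect_equal(nrow(sk1$edges), 0L)

  # disjoint labels skeletonize per component
  ml <- make_multilabel_volume(radii = c(4, 3, 3))
  skm <- skeletonize(ml$volume)
  expect_length(skm$roots, 3L)
})

test_that("skeleton_length sums physical edge lengths", {
  sk <- skeleton3d(rbind(c(0, 0, 0), c(3, 4, 0)), c(1, 1),
                   matrix(c(1L, 2L), 1L), roots = 1L)
  expect_equal(skeleton_length(sk), 5)
  empty <- skeleton3d(matrix(0, 0, 3), numeric(), matrix(0L, 0, 2))
  expect_equal(skeleton_length(empty), 0)
})

test_that("the distance-to-boundary field respects anisotropic spacing", {
  arr <- array(1L, c(5, 5, 5))
  vol <- label_volume(arr, spacing = c(4, 1, 1))
  d <- distance_to_boundary(vol)
  # centre voxel: 2 voxels from each face; z costs 4/voxel but y/x win
  expect_equal(d[3, 3, 3], 3)
  # a z-face voxel is 1 z-step (cost 4) or >= 3 in-plane steps away
  expect_equal(d[1, 3, 3], 3)
  vol_iso <- label_volume(arr)
  expect_equal(distance_to_boundary(vol_iso)[3, 3, 3], 3)
  expect_equal(distance_to_boundary(vol_iso)[1, 3, 3], 1)
})
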