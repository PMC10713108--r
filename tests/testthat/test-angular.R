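test_that("a point-like object subtends vanishing angles", {
  tiny <- make_icosphere(radius = 1e-6, subdivisions = 2)$mesh
  res <- angular_distribution(tiny, reference = c(10, 0, 0),
                              fixed = c(0, 0, 0), n_samples = 2000)
  expect_lte(res$mean_angle, 1e-4)
  expect_lte(res$std_angle, 1e-4)
})

test_that("sphere angles respect the geometric bound and match the oracle", {
  s2 <- fx_icosphere(2, 3)$mesh
  ref <- c(10, 0, 0)
  res <- angular_distribution(s2, reference = ref, fixed = c(0, 0, 0),
                              n_samples = 10000, seed = 1)
  # every sample lies within the ball of radius 2 around the fixed point
  expect_lte(max(attr(res, "angles")), asin(2 / 10) * 1.02)

  # independent 1e6-sample oracle (different sampler and RNG stream)
  osm <- oracle_surface_samples(s2, 1e6, seed = 99)
  oang <- oracle_angles(osm, ref, c(0, 0, 0))
  se_mean <- stats::sd(oang) / sqrt(10000)
  expect_lt(abs(res$mean_angle - mean(oang)), 3 * se_mean)
  o_sd <- sqrt(mean((oang - mean(oang))^2))
  se_sd <- o_sd / sqrt(2 * 10000)         # large-sample SE of a std dev
  expect_lt(abs(res$std_angle - o_sd), 3 * se_sd)
})

test_that("two antipodal small shells centre the distribution at 90 degrees", {
  shell <- make_icosphere(radius = 0.05, subdivisions = 2,
                          center = c(0, 5, 0))$mesh
  shell2 <- make_icosphere(radius = 0.05, subdivisions = 2,
                           center = c(0, -5, 0))$mesh
  both <- merge_meshes(shell, shell2)
  res <- angular_distribution(both, reference = c(0, 0, 0),
                              fixed = c(1, 0, 0), n_samples = 4000)
  expect_equal(res$mean_angle, pi / 2, tolerance = 0.02)
  expect_lt(res$std_angle, 0.05)
})

test_that("angular spread shrinks with distance and grows with object size", {
  s2 <- fx_icosphere(2, 3)$mesh
  near <- angular_distribution(s2, reference = c(10, 0, 0),
                               fixed = c(0, 0, 0), n_samples = 5000)
  far <- angular_distribution(s2, reference = c(20, 0, 0),
                              fixed = c(0, 0, 0), n_samples = 5000)
  expect_lt(far$std_angle, near$std_angle)

  s1 <- fx_icosphere(1, 3)$mesh
  s4 <- fx_icosphere(4, 3)$mesh
  small <- angular_distribution(s1, reference = c(10, 0, 0),
                                fixed = c(0, 0, 0), n_samples = 5000)
  large <- angular_distribution(s4, reference = c(10, 0, 0),
                                fixed = c(0, 0, 0), n_samples = 5000)
  expect_gt(large$mean_angle, small$mean_angle)
})

test_that("the statistic is rotation invariant and seed deterministic", {
  s2 <- fx_icosphere(2, 3)$mesh
  ref <- c(10, 0, 0); fix <- c(0, 0, 0)
  base <- angular_distribution(s2, ref, fix, n_samples = 10000, seed = 0)
  set.seed(31)
  rot <- random_rotation()
  res <- angular_distribution(transform_mesh(s2, rot),
                              drop(rot %*% ref), drop(rot %*% fix),
                              n_samples = 10000, seed = 0)
  expect_lt(abs(res$mean_angle - base$mean_angle), 1e-6)
  expect_lt(abs(res$std_angle - base$std_angle), 1e-6)

  again <- angular_distribution(s2, ref, fix, n_samples = 10000, seed = 0)
  expect_identical(base$mean_angle, again$mean_angle)
  expect_identical(base$std_angle, again$std_angle)

  other <- angular_distribution(s2, ref, fix, n_samples = 10000, seed = 42)
  se <- base$std_angle / sqrt(10000)
  expect_lt(abs(other$mean_angle - base$mean_angle), 4 * sqrt(2) * se)
})

test_that("degenerate anchor configurations error out", {
  s2 <- fx_icosphere(2, 3)$mesh
  expect_error(angular_distribution(s2, reference = c(0, 0, 0),
                                    fixed = c(0, 0, 0)), "coincides")
  expect_error(angular_distribution(s2, c(10, 0, 0), n_samples = 0),
               "n_samples")
})

test_that("vertex-mode sampling is available and consistent", {
  s2 <- fx_icosphere(2, 3)$mesh
  va <- angular_distribution(s2, c(10, 0, 0), c(0, 0, 0),
                             n_samples = 5000, mode = "vertices")
  ar <- angular_distribution(s2, c(10, 0, 0), c(0, 0, 0), n_samples = 5000)
  # on a uniform icosphere the two modes agree closely
  expect_equal(va$mean_angle, ar$mean_angle, tolerance = 0.02)
})
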