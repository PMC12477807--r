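test_that("simulation is deterministic under seed and respects margins", {
  p <- sim_params(dims = c(64L, 64L, 8L), n_spots = 15L, seed = 42L)
  a <- simulate_stack(p)
  b <- simulate_stack(p)
  expect_identical(punctate:::raw_voxels(a$stack), punctate:::raw_voxels(b$stack))
  expect_equal(a$truth, b$truth)

  expect_true(all(a$truth$x > 7 & a$truth$x <= 64 - 7))
  expect_true(all(a$truth$y > 7 & a$truth$y <= 64 - 7))
  expect_true(all(a$truth$z >= 1 & a$truth$z <= 8))
  expect_true(all(punctate:::raw_voxels(a$stack) >= 0))
  expect_true(all(punctate:::raw_voxels(a$stack) ==
                    round(punctate:::raw_voxels(a$stack))))

  # zero spots: pure noise, empty truth
  p0 <- sim_params(dims = c(32L, 32L, 4L), n_spots = 0L, seed = 3L)
  s0 <- simulate_stack(p0)
  expect_equal(nrow(s0$truth), 0L)

  # margins too tight for the frame
  expect_error(simulate_stack(sim_params(dims = c(12L, 12L, 4L), margin_xy = 7L)),
               "margins")
})

test_that("clustered spots are placed near their cluster centers", {
  p <- sim_params(dims = c(96L, 96L, 8L), n_spots = 5L, n_clusters = 2L,
                  spots_per_cluster = 6L, cluster_radius = 4, seed = 9L)
  sim <- simulate_stack(p)
  expect_equal(nrow(sim$truth), 5L + 12L)
  expect_equal(sum(sim$truth$clustered), 12L)
  cl <- dplyr::filter(sim$truth, clustered)
  # within each cluster, spread is bounded by the cluster diameter
  d <- as.matrix(dist(cbind(cl$x[1:6], cl$y[1:6])))
  expect_lte(max(d), 2 * p$cluster_radius + 1e-9)
})

test_that("high-SNR stacks are fully recovered at the selected threshold", {
  # low but nonzero background noise: the count curve has the noise arm the
  # threshold selector is built around, and all spots are recovered cleanly
  p <- sim_params(dims = c(96L, 96L, 10L), n_spots = 10L, bg_sd = 20,
                  amp_mean = 800, amp_rel_var = 0.1, seed = 21L)
  sim <- simulate_stack(p)
  det <- detect_spots(sim$stack)
  thr <- select_threshold(det$curve)
  retained <- dplyr::filter(det$calls, intensity >= thr$selected)
  m <- match_calls(retained, sim$truth)
  expect_equal(c(m$tp, m$fp, m$fn), c(10L, 0L, 0L))

  # strictly noiseless degenerate limit: the count curve has no noise arm,
  # so the image is ZVP-flagged as too clean; detection itself is perfect
  # (all 10 spots are base maxima with no false calls) even though the
  # elbow heuristic has no noise/signal boundary to find
  p0 <- sim_params(dims = c(96L, 96L, 10L), n_spots = 10L, bg_sd = 0,
                   amp_mean = 800, amp_rel_var = 0.1, seed = 21L)
  sim0 <- simulate_stack(p0)
  det0 <- detect_spots(sim0$stack)
  expect_true(det0$zvp_flagged)
  m0 <- match_calls(det0$calls, sim0$truth)
  expect_equal(c(m0$tp, m0$fp, m0$fn), c(10L, 0L, 0L))
})

test_that("the 3D blur conserves interior mass and widens spots", {
  v <- array(0, c(40, 40, 9))
  v[20, 20, 5] <- 1000
  blurred <- apply_gfp_blur(image_stack(v))
  bv <- punctate:::raw_voxels(blurred)
  expect_equal(sum(bv), 1000, tolerance = 1e-6)
  expect_lt(max(bv), 1000)  # never increases the maximum
  expect_equal(which.max(bv[, , 5]), which.max(v[, , 5]))

  # a blurred Gaussian spot fits wider than the original
  v2 <- inject_spot(array(0, c(41, 41, 9)), 21, 21, 5, A = 800,
                    sigma_xy = 1.3, sigma_z = 0.9)
  w0 <- fit_spot(image_stack(v2), 21, 21, 5)$sigma_xy
  w1 <- fit_spot(apply_gfp_blur(image_stack(v2)), 21, 21, 5)$sigma_xy
  expect_gt(w1, w0)

  expect_error(apply_gfp_blur(image_stack(array(1, c(40, 40, 3)))), "thinner")
})

test_that("edge darkening attenuates corners, spares the center, stays in bounds", {
  v <- array(1000, c(41, 41, 3))
  set.seed(1)
  fs <- vapply(1:500, function(s) apply_edge_darkening(image_stack(v), seed = s)$factor,
               double(1L))
  expect_gte(min(fs), 0.01)
  expect_lte(max(fs), 0.10)

  res <- apply_edge_darkening(image_stack(v), seed = 7L)
  out <- punctate:::raw_voxels(res$stack)
  # center pixel: attenuation 1, only the +/-5% noise remains
  expect_lt(abs(out[21, 21, 1] - 1000) / 1000, 0.05 + 1e-9)
  # corner attenuation approaches 1 - f
  corner <- out[1, 1, 1] / 1000
  expect_lt(abs(corner - (1 - res$factor)), 0.05 + 1e-9)
  expect_lte(max(out), 1050)  # never exceeds input by more than filter noise
  expect_true(all(out >= 0))
})

test_that("defocus spares the center plane and blurs the extremes most", {
  set.seed(2)
  v <- array(rnorm(31 * 31 * 9, 500, 80), c(31, 31, 9))
  v[v < 0] <- 0
  res <- apply_defocus(image_stack(v), seed = 11L)
  out <- punctate:::raw_voxels(res$stack)
  expect_gte(res$max_strength, 1.1)
  expect_lte(res$max_strength, 2.5)
  expect_equal(out[, , 5], v[, , 5])  # center plane untouched
  # local variance drops more at the extreme planes than near the center
  drop <- function(z) var(as.vector(v[, , z])) - var(as.vector(out[, , z]))
  expect_gt(drop(1), drop(4))
  expect_gt(drop(9), drop(6))
  expect_lte(max(out), max(v))  # degradation never increases the maximum

  expect_error(apply_defocus(image_stack(array(1, c(31, 31, 2)))), "3 planes")
})
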