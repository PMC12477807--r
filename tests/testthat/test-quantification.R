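test_that("Gaussian fitting recovers amplitude and subpixel center on noiseless spots", {
  v <- array(50, c(21, 21, 9))
  v <- inject_spot(v, 11, 11, 5, A = 500, sigma_xy = 1.5, sigma_z = 1.0)
  fit <- fit_spot(image_stack(round(v)), 11, 11, 5)
  expect_true(fit$converged)
  expect_lt(abs(fit$amplitude - 500) / 500, 0.05)
  expect_lt(abs(fit$x0 - 11), 0.1)
  expect_lt(abs(fit$y0 - 11), 0.1)
  expect_lt(abs(fit$z0 - 5), 0.3)
  expect_lt(abs(fit$sigma_xy - 1.5), 0.2)

  # subpixel shift is reflected in the fitted center
  v2 <- array(50, c(21, 21, 9))
  v2 <- inject_spot(v2, 11.4, 11, 5, A = 500, sigma_xy = 1.5, sigma_z = 1.0)
  fit2 <- fit_spot(image_stack(round(v2)), 11, 11, 5)
  expect_lt(abs(fit2$x0 - 11.4), 0.15)

  # flat crop falls back and is flagged
  flat <- fit_spot(image_stack(array(10, c(15, 15, 5))), 8, 8, 3)
  expect_false(flat$converged)
})

test_that("fit accuracy holds in the median over many noiseless spots and degrades with noise", {
  set.seed(77)
  n <- 40
  amp_err <- ctr_err <- numeric(n)
  for (i in seq_len(n)) {
    x0 <- runif(1, 9, 12); y0 <- runif(1, 9, 12)
    A <- runif(1, 200, 900)
    v <- array(100, c(21, 21, 7))
    v <- inject_spot(v, x0, y0, 4, A = A, sigma_xy = 1.3, sigma_z = 0.9)
    fit <- fit_spot(image_stack(round(v)), round(x0), round(y0), 4)
    amp_err[i] <- abs(fit$amplitude - A) / A
    ctr_err[i] <- sqrt((fit$x0 - x0)^2 + (fit$y0 - y0)^2)
  }
  expect_lte(median(amp_err), 0.1)
  expect_lte(median(ctr_err), 0.2)

  # with heavy noise the center error grows (graceful degradation)
  set.seed(78)
  noisy_err <- vapply(1:10, function(i) {
    v <- array(100, c(21, 21, 7)) + array(rnorm(21 * 21 * 7, 0, 60), c(21, 21, 7))
    v[v < 0] <- 0
    v <- inject_spot(v, 10.5, 10.5, 4, A = 300, sigma_xy = 1.3, sigma_z = 0.9)
    fit <- fit_spot(image_stack(round(v)), 10, 10, 4)
    sqrt((fit$x0 - 10.5)^2 + (fit$y0 - 10.5)^2)
  }, double(1L))
  expect_gt(median(noisy_err), median(ctr_err))
})

test_that("ellipsoid integration tracks injected signal, clamps at background, scales linearly", {
  v0 <- array(0, c(21, 21, 9))
  v <- inject_spot(v0, 11, 11, 5, A = 600, sigma_xy = 1.4, sigma_z = 1.0)
  st <- image_stack(v)
  fit <- fit_spot(st, 11, 11, 5)
  # oracle: direct sum of the noiseless image inside the same ellipsoid
  oracle <- integrate_signal(st, fit)
  # crop-border median on a pure Gaussian stays near zero
  expect_lt(fit$background, 5)
  truth_sum <- {
    rxy <- 2 * sqrt(2 * log(2)) * fit$sigma_xy
    rz <- max(fit$z_extent / 2, 1)
    s <- 0
    for (z in 1:9) for (x in 1:21) for (y in 1:21) {
      if (((x - fit$x0)^2 + (y - fit$y0)^2) / rxy^2 +
          (z - fit$z0)^2 / rz^2 <= 1) s <- s + v[y, x, z]
    }
    s
  }
  expect_lt(abs(oracle - truth_sum) / truth_sum, 0.15)

  # background above every voxel clamps to zero
  spot_hi <- fit
  spot_hi$background <- 1e6
  expect_equal(integrate_signal(st, spot_hi), 0)

  # doubling the amplitude doubles the integral (same fitted geometry)
  v2 <- inject_spot(v0, 11, 11, 5, A = 1200, sigma_xy = 1.4, sigma_z = 1.0)
  expect_equal(integrate_signal(image_stack(v2), fit), 2 * oracle,
               tolerance = 0.01)
})

test_that("per-cell counting assigns by mask label and conserves total calls", {
  mask <- matrix(0L, 20, 20)
  mask[2:8, 2:8] <- 1L     # cell 1
  mask[12:18, 12:18] <- 2L # cell 2
  calls <- tibble::tibble(
    x = c(3, 4, 5, 14, 10), y = c(3, 4, 5, 14, 10), z = rep(1L, 5),
    intensity = 100)
  cells <- count_per_cell(calls, mask, cutoff = 2L)
  expect_equal(cells$count[cells$cell_id == 1], 3L)
  expect_equal(cells$count[cells$cell_id == 2], 1L)
  expect_equal(cells$is_on, c(TRUE, FALSE))
  expect_equal(attr(cells, "background_calls"), 1L)
  expect_equal(sum(cells$count) + attr(cells, "background_calls"), nrow(calls))

  # empty call table: all cells zero, none ON
  none <- count_per_cell(calls[0, ], mask, cutoff = 2L)
  expect_equal(none$count, c(0L, 0L))
  expect_false(any(none$is_on))

  # calls outside the mask dimensions error
  bad <- tibble::tibble(x = 25, y = 3, z = 1L, intensity = 1)
  expect_error(count_per_cell(bad, mask), "mismatch")
})

test_that("ON-cell statistics use an inclusive cutoff", {
  cells <- tibble::tibble(cell_id = 1:3, count = c(7L, 9L, 2L),
                          is_on = c(7, 9, 2) >= 8)
  s <- on_cell_stats(cells)
  expect_equal(s$on_proportion, 1 / 3)
  expect_equal(s$mean_count_among_on, 9)

  low <- dplyr::mutate(cells, is_on = count >= 100)
  s2 <- on_cell_stats(low)
  expect_equal(s2$on_proportion, 0)
  expect_true(is.na(s2$mean_count_among_on))

  at <- tibble::tibble(cell_id = 1:3, count = rep(8L, 3), is_on = rep(TRUE, 3))
  expect_equal(on_cell_stats(at)$on_proportion, 1)

  expect_error(on_cell_stats(cells[0, ]), "Empty")
})

test_that("background mask separates flat background from z-variable cell regions", {
  set.seed(55)
  H <- 60; W <- 60; D <- 10
  v <- array(rnorm(H * W * D, 100, 2), c(H, W, D))  # flat background over z
  cellpix <- matrix(FALSE, H, W)
  cellpix[15:45, 15:45] <- TRUE
  for (z in seq_len(D)) {
    sl <- v[, , z]
    sl[cellpix] <- sl[cellpix] + rnorm(sum(cellpix), 0, 40)  # focus variation
    v[, , z] <- sl
  }
  v[v < 0] <- 0
  cellmask <- matrix(0L, H, W)
  cellmask[cellpix] <- 1L
  bg <- derive_background_mask(image_stack(v), cellmask)
  truth_bg <- !cellpix
  expect_gte(sum(bg & truth_bg) / sum(truth_bg), 0.95)
  # never overlaps cells
  expect_false(any(bg & cellpix))

  # empty cell mask on an all-background image: nearly the whole frame
  v2 <- array(rnorm(H * W * D, 100, 2), c(H, W, D))
  v2[v2 < 0] <- 0
  bg2 <- derive_background_mask(image_stack(v2), matrix(0L, H, W))
  expect_gte(mean(bg2), 0.9)

  expect_error(derive_background_mask(image_stack(matrix(1, 5, 5)), matrix(0L, 5, 5)),
               "multi-slice")
})

test_that("small holes enclosed by background are filled", {
  set.seed(56)
  H <- 40; W <- 40; D <- 8
  v <- array(rnorm(H * W * D, 100, 2), c(H, W, D))
  # a 10-px high-variance speck in open background
  speck <- matrix(FALSE, H, W); speck[20:21, 20:24] <- TRUE
  for (z in seq_len(D)) {
    sl <- v[, , z]; sl[speck] <- sl[speck] + rnorm(sum(speck), 0, 50)
    v[, , z] <- sl
  }
  v[v < 0] <- 0
  bg <- derive_background_mask(image_stack(v), matrix(0L, H, W))
  expect_true(all(bg[speck]))
})
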