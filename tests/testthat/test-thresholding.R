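test_that("difference curve trims everything before its peak", {
  c1 <- tibble::tibble(threshold = 1:4, count = c(100L, 10L, 9L, 8L))
  d1 <- diff_and_trim(c1)
  expect_equal(d1$d, c(90, 1, 1))
  expect_equal(d1$threshold, 1:3)

  c2 <- tibble::tibble(threshold = 1:4, count = c(50L, 50L, 40L, 39L))
  d2 <- diff_and_trim(c2)
  expect_equal(d2$threshold[1L], 2L)  # first entry (zero diff) trimmed
  expect_equal(d2$d[1L], 10)

  flat <- tibble::tibble(threshold = 1:5, count = rep(7L, 5))
  expect_error(diff_and_trim(flat), "Flat")
})

test_that("Fano window scores use population variance over mean, zero for flat windows", {
  dc <- tibble::tibble(threshold = 1:3, d = c(5, 5, 5))
  tc <- fano_window_scores(dc, window_sizes = 3L)[[1L]]
  expect_equal(tc$value, c(0, 0, 0))

  dc2 <- tibble::tibble(threshold = 1:2, d = c(0, 10))
  tc2 <- fano_window_scores(dc2, window_sizes = 2L)[[1L]]
  # full window at the position whose window covers both points: var 25, mean 5
  expect_true(5 %in% tc2$value)

  # window size equal to curve length: the full-window position scores the
  # global Fano factor of the whole difference curve
  dc3 <- tibble::tibble(threshold = 1:6, d = c(9, 1, 4, 4, 1, 9))
  tc3 <- fano_window_scores(dc3, window_sizes = 6L)[[1L]]
  g_fano <- mean((dc3$d - mean(dc3$d))^2) / mean(dc3$d)
  expect_equal(tc3$value[3L], g_fano)

  expect_error(fano_window_scores(dc3, window_sizes = 99L), "out of range")
})

test_that("MAD candidates pick the lowest threshold at or below the cutoff", {
  # strictly decreasing scores: k = 0 candidate is the first y <= median
  tc <- structure(tibble::tibble(threshold = 10:19, value = 10^(10:1) - 1),
                  window_size = 5L, class = c("transformed_curve", class(tibble::tibble())))
  y <- log10(tc$value + 1)
  cand <- mad_candidates(tc, k_set = 0)
  expect_equal(cand$threshold, tc$threshold[which(y <= median(y))[1L]])

  # constant curve: MAD degenerates; k >= 0 hits the first threshold, k < 0 none
  tcc <- structure(tibble::tibble(threshold = 1:6, value = rep(3, 6)),
                   window_size = 5L, class = class(tc))
  cc <- mad_candidates(tcc)
  expect_true(all(cc$threshold == 1L))
  expect_true(all(cc$mad_factor >= 0))

  # default factor grid emits at most 9 candidates
  expect_lte(nrow(mad_candidates(tc)), 9L)
})

test_that("two-piece fit finds constructed kinks and shifts with translation", {
  # piecewise-linear in log space with a kink at threshold 40
  th <- 11:70
  y <- ifelse(th <= 40, 8 - 0.18 * (th - 11), 2.78 - 0.01 * (th - 40))
  tc <- structure(tibble::tibble(threshold = th, value = 10^y - 1),
                  window_size = 5L,
                  class = c("transformed_curve", class(tibble::tibble())))
  curve <- tibble::tibble(threshold = th, count = as.integer(round(10^y)))
  cand <- two_piece_fit_candidates(tc, curve)
  bp <- cand$threshold[cand$source == "fit_breakpoint"]
  expect_lte(abs(bp - 40), 2)

  tc2 <- tc
  tc2$threshold <- tc$threshold + 10L
  curve2 <- curve
  curve2$threshold <- curve$threshold + 10L
  cand2 <- two_piece_fit_candidates(tc2, curve2)
  expect_equal(cand2$threshold[cand2$source == "fit_breakpoint"], bp + 10L)

  short <- structure(tibble::tibble(threshold = 1:4, value = 1:4),
                     window_size = 5L, class = class(tc))
  expect_equal(nrow(two_piece_fit_candidates(short, curve)), 0L)
})

test_that("MAD candidates are invariant to scaling all counts", {
  curve <- curve_low_expression()
  pick_mads <- function(cv) {
    dc <- diff_and_trim(cv)
    tc <- fano_window_scores(dc, window_sizes = 10L)[[1L]]
    mad_candidates(tc)
  }
  a <- pick_mads(curve)
  scaled <- dplyr::mutate(curve, count = count * 10L)
  b <- pick_mads(scaled)
  expect_equal(a$threshold, b$threshold)
})

test_that("selected thresholds land in the construction-defined signal regions", {
  # high expression: noise collapse ends well before the plateau's second
  # drop at threshold 150
  hi <- select_threshold(curve_high_expression())
  expect_gte(hi$selected, 15)
  expect_lte(hi$selected, 150)

  # low expression L-curve: selection clears the steep noise arm
  lo <- select_threshold(curve_low_expression())
  expect_gte(lo$selected, 15)
  expect_lte(lo$selected, 290)

  # variable intensity: a gradual bend still yields an in-range selection
  vi <- select_threshold(curve_variable_intensity())
  expect_gte(vi$selected, vi$pool_min)
  expect_lte(vi$selected, vi$pool_max)

  for (res in list(hi, lo, vi)) {
    expect_gte(res$selected, res$pool_min)
    expect_lte(res$selected, res$pool_max)
  }
})

test_that("presets move the selection monotonically from recall to precision", {
  curve <- curve_high_expression()
  sel <- vapply(c("recall-strong", "recall", "default", "precision",
                  "precision-strong"),
                function(p) select_threshold(curve, preset = p)$selected,
                integer(1L))
  expect_true(all(diff(sel) >= 0))

  expect_error(select_threshold(curve, preset = "nope"), "preset")
})

test_that("threshold results expose tidy() and glance() summaries", {
  res <- select_threshold(curve_high_expression())
  td <- tidy(res)
  expect_true(all(c("threshold", "source", "window_size") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$selected, res$selected)
  expect_equal(gl$pool_n, nrow(res$pool))
})
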