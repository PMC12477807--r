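#' Difference curve of a spot count curve, trimmed to its peak
#'
#' Takes the first-derivative approximation of the count curve (absolute
#' difference between adjacent counts, attributed to the left threshold of
#' each pair) and removes entries below the threshold of the peak magnitude
#' so the transformed curve begins at its highest point.
#'
#' @param curve a `spot_count_curve` from [counts_vs_threshold()] (or any
#'   tibble with `threshold` and `count`).
#' @return Tibble with columns `threshold`, `d`.
#' @export
diff_and_trim <- function(curve) {
  if (nrow(curve) < 3L) abort("Count curve must have at least 3 points.")
  d <- abs(diff(curve$count))
  if (all(d == 0)) abort("Flat spot count curve: cannot select a threshold.")
  th <- curve$threshold[-nrow(curve)]
  peak <- which.max(d)
  tibble(threshold = th[peak:length(th)], d = as.double(d[peak:length(d)]))
}

#' Sliding-window Fano-factor scores of the difference curve
#'
#' For each window size, scores every position of the trimmed difference
#' curve with the Fano factor (population variance / mean) of the values in
#' a centered window of that width, shrunk at the curve ends. Windows with
#' zero mean score zero. The Fano transform normalizes local curve topology
#' to the magnitude of counts, which keeps candidate placement comparable
#' across images with very different spot numbers.
#'
#' @param diff_curve tibble from [diff_and_trim()].
#' @param window_sizes integer vector of window widths (each >= 2 and <=
#'   curve length).
#' @return A list of `transformed_curve` tibbles (`threshold`, `value`),
#'   one per window size, each with a `window_size` attribute.
#' @export
fano_window_scores <- function(diff_curve, window_sizes = c(5L, 10L, 15L, 20L)) {
  n <- nrow(diff_curve)
  d <- diff_curve$d
  lapply(window_sizes, function(w) {
    if (w < 2L || w > n) abort(sprintf("Window size %d out of range [2, %d].", w, n))
    lo <- pmax(1L, seq_len(n) - ((w - 1L) %/% 2L))
    hi <- pmin(n, seq_len(n) + (w %/% 2L))
    val <- vapply(seq_len(n), function(i) {
      win <- d[lo[i]:hi[i]]
      m <- mean(win)
      if (m == 0) 0 else mean((win - m)^2) / m
    }, double(1L))
    structure(tibble(threshold = diff_curve$threshold, value = val),
              window_size = as.integer(w),
              class = c("transformed_curve", class(tibble())))
  })
}

#' MAD-based threshold candidates from a transformed curve
#'
#' Works on the log10 projection `y = log10(value + 1)` of the window-score
#' curve. For each factor `k`, the candidate is the lowest threshold whose
#' `y` falls at or below `median(y) + k * MAD(y)` (unscaled median absolute
#' deviation). Factors with no qualifying point emit nothing; when the MAD
#' degenerates to zero, negative factors emit nothing.
#'
#' @param tc a `transformed_curve` from [fano_window_scores()].
#' @param k_set numeric MAD factors (default -1 to 1 in steps of 0.25).
#' @return Tibble of candidates: `threshold`, `source`, `window_size`,
#'   `mad_factor`.
#' @export
mad_candidates <- function(tc, k_set = seq(-1, 1, by = 0.25)) {
  if (nrow(tc) == 0L) abort("Transformed curve is empty.")
  y <- log10(tc$value + 1)
  med <- median(y)
  madev <- median(abs(y - med))
  out <- lapply(k_set, function(k) {
    if (k < 0 && madev == 0) return(NULL)
    idx <- which(y <= med + k * madev)
    if (length(idx) == 0L) return(NULL)
    tibble(threshold = tc$threshold[idx[1L]], source = "mad",
           window_size = attr(tc, "window_size") %||% NA_integer_,
           mad_factor = k)
  })
  bind_rows(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# closed-form OLS SSE of y ~ x over an index range
.seg_sse <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) return(sum((y - my)^2))
  b <- sum((x - mx) * (y - my)) / sxx
  sum((y - my - b * (x - mx))^2)
}

.seg_fit <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- if (sxx == 0) 0 else sum((x - mx) * (y - my)) / sxx
  c(intercept = my - slope * mx, slope = slope)
}

#' Two-piece linear fit threshold candidates
#'
#' Fits two independent least-squares lines to the (by default log10-
#' projected) window-score curve, choosing the breakpoint by exhaustive
#' search over interior positions (at least 3 points per piece) to minimize
#' the summed squared residuals. Two candidates are emitted: the threshold
#' at the breakpoint, and the leftmost threshold where the right-hand fit
#' line first meets or crosses the log10 projection of the original spot
#' count curve.
#'
#' @param tc a `transformed_curve` from [fano_window_scores()].
#' @param curve the original `spot_count_curve`.
#' @param fit_log fit on `log10(value + 1)` (default) or the raw values.
#' @return Tibble of candidates (`threshold`, `source`, `window_size`,
#'   `mad_factor` = NA); empty when the fit is degenerate.
#' @export
two_piece_fit_candidates <- function(tc, curve, fit_log = TRUE) {
  n <- nrow(tc)
  empty <- tibble(threshold = integer(), source = character(),
                  window_size = integer(), mad_factor = double())
  if (n < 5L) return(empty)
  x <- as.double(tc$threshold)
  y <- if (fit_log) log10(tc$value + 1) else tc$value
  bs <- 3L:(n - 2L)
  sse <- vapply(bs, function(b) {
    .seg_sse(x[1:b], y[1:b]) + .seg_sse(x[b:n], y[b:n])
  }, double(1L))
  b <- bs[which.min(sse)]
  fit_r <- .seg_fit(x[b:n], y[b:n])
  cands <- tibble(threshold = tc$threshold[b], source = "fit_breakpoint",
                  window_size = attr(tc, "window_size") %||% NA_integer_,
                  mad_factor = NA_real_)
  # leftmost meeting/crossing of the right-hand line with the count curve
  ct <- as.double(curve$threshold)
  cy <- log10(curve$count + 1)
  line_y <- fit_r[["intercept"]] + fit_r[["slope"]] * ct
  g <- line_y - cy
  hit <- which(g == 0)
  cross <- which(g[-1] * g[-length(g)] < 0)
  first <- suppressWarnings(min(c(hit, cross + 1L)))
  if (is.finite(first)) {
    cands <- bind_rows(cands, tibble(
      threshold = curve$threshold[first], source = "fit_intersection",
      window_size = attr(tc, "window_size") %||% NA_integer_,
      mad_factor = NA_real_))
  }
  cands
}

.preset_lambda <- c("recall-strong" = -1, "recall" = -0.5, "default" = 0,
                    "precision" = 0.5, "precision-strong" = 1)

#' Automatic threshold selection from a spot count curve
#'
#' Transforms the count curve (difference, peak trim, sliding-window Fano
#' scores at several window sizes), pools MAD-based and two-piece-fit
#' candidates from every window size, and combines the pool into a single
#' integer threshold by a weighted average. Presets shift the selection
#' within the pool: `selected = round(wmean + lambda * sd)` with `lambda`
#' -1, -0.5, 0, 0.5, 1 for presets `recall-strong`, `recall`, `default`,
#' `precision`, `precision-strong`, clamped to the pool range.
#'
#' @param curve a `spot_count_curve`.
#' @param preset one of `"default"`, `"precision"`, `"precision-strong"`,
#'   `"recall"`, `"recall-strong"`.
#' @param window_sizes Fano window widths (silently reduced to the sizes
#'   that fit the trimmed curve).
#' @param mad_factors MAD factors for [mad_candidates()].
#' @param weights named per-source candidate weights
#'   (`mad`, `fit_breakpoint`, `fit_intersection`).
#' @param fit_log passed to [two_piece_fit_candidates()].
#' @return A `threshold_result`: list with `selected`, candidate `pool`
#'   tibble, `pool_min`, `pool_max`, `pool_mean`, `pool_sd`, `preset`,
#'   `lambda`.
#' @export
select_threshold <- function(curve, preset = "default",
                             window_sizes = c(5L, 10L, 15L, 20L),
                             mad_factors = seq(-1, 1, by = 0.25),
                             weights = c(mad = 1, fit_breakpoint = 1,
                                         fit_intersection = 1),
                             fit_log = TRUE) {
  if (!preset %in% names(.preset_lambda)) {
    abort(sprintf("Unknown preset '%s'.", preset))
  }
  dc <- diff_and_trim(curve)
  window_sizes <- window_sizes[window_sizes >= 2L & window_sizes <= nrow(dc)]
  if (length(window_sizes) == 0L) window_sizes <- min(2L, nrow(dc))
  tcs <- fano_window_scores(dc, window_sizes)
  pool <- bind_rows(lapply(tcs, function(tc) {
    bind_rows(mad_candidates(tc, mad_factors),
              two_piece_fit_candidates(tc, curve, fit_log = fit_log))
  }))
  if (nrow(pool) == 0L) abort("Auto thresholding failed: empty candidate pool.")
  w <- unname(weights[pool$source])
  w[is.na(w)] <- 1
  wmean <- sum(w * pool$threshold) / sum(w)
  psd <- if (nrow(pool) > 1L) sd(pool$threshold) else 0
  lambda <- .preset_lambda[[preset]]
  sel <- round(wmean + lambda * psd)
  sel <- min(max(sel, min(pool$threshold)), max(pool$threshold))
  sel <- min(max(sel, min(curve$threshold)), max(curve$threshold))
  structure(list(selected = as.integer(sel), pool = pool,
                 pool_min = min(pool$threshold), pool_max = max(pool$threshold),
                 pool_mean = mean(pool$threshold), pool_sd = psd,
                 preset = preset, lambda = lambda),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> selected %d (preset %s; pool n=%d, %d..%d, mean %.1f +/- %.1f)\n",
              x$selected, x$preset, nrow(x$pool), x$pool_min, x$pool_max,
              x$pool_mean, x$pool_sd))
  invisible(x)
}

#' @export
tidy.threshold_result <- function(x, ...) x$pool

#' @export
glance.threshold_result <- function(x, ...) {
  tibble(selected = x$selected, pool_n = nrow(x$pool), pool_min = x$pool_min,
         pool_max = x$pool_max, pool_mean = x$pool_mean, pool_sd = x$pool_sd,
         preset = x$preset, lambda = x$lambda)
}
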