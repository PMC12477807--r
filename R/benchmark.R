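#' Match a call set against a reference set
#'
#' Candidate pairs are call/reference pairs within a Euclidean xy distance
#' of `max_xy` voxels (inclusive) and at most `max_z` z-planes apart
#' (inclusive). Pairs are sorted by ascending xy distance, then |dz|, then
#' call index, and accepted greedily one-to-one: a reference already matched
#' with a closer call is not matched again. Leftover calls are false
#' positives, leftover references false negatives.
#'
#' @param calls,ref call tables (tibbles with `x`, `y`, `z`), same
#'   coordinate base.
#' @param max_xy,max_z matching tolerances (voxels / planes).
#' @return A `match_result`: list with `pairs` (tibble `call_idx`,
#'   `ref_idx`, `dist_xy`, `dz`), `tp`, `fp`, `fn`.
#' @export
match_calls <- function(calls, ref, max_xy = 4, max_z = 2) {
  nc <- nrow(calls); nr <- nrow(ref)
  pairs <- candidate_pairs(calls, ref, max_xy, max_z)
  m <- greedy_match(pairs, rep(TRUE, nc), nc, nr)
  structure(list(pairs = m$pairs, tp = m$tp, fp = nc - m$tp, fn = nr - m$tp),
            class = "match_result")
}

# all call/ref pairs within tolerance, sorted by (dist_xy, |dz|, call index)
candidate_pairs <- function(calls, ref, max_xy = 4, max_z = 2) {
  empty <- tibble(call_idx = integer(), ref_idx = integer(),
                  dist_xy = double(), dz = integer())
  if (nrow(calls) == 0L || nrow(ref) == 0L) return(empty)
  out <- vector("list", nrow(ref))
  for (j in seq_len(nrow(ref))) {
    dz <- abs(calls$z - ref$z[j])
    dxy2 <- (calls$x - ref$x[j])^2 + (calls$y - ref$y[j])^2
    hit <- which(dz <= max_z & dxy2 <= max_xy^2)
    if (length(hit) > 0L) {
      out[[j]] <- tibble(call_idx = hit, ref_idx = j,
                         dist_xy = sqrt(dxy2[hit]), dz = as.integer(dz[hit]))
    }
  }
  p <- bind_rows(out)
  if (nrow(p) == 0L) return(empty)
  p[order(p$dist_xy, abs(p$dz), p$call_idx), ]
}

# greedy one-to-one acceptance over pre-sorted pairs, restricted to active calls
greedy_match <- function(pairs, call_active, nc, nr) {
  used_call <- rep(FALSE, nc)
  used_ref <- rep(FALSE, nr)
  keep <- integer(0)
  if (nrow(pairs) > 0L) {
    ci <- pairs$call_idx; ri <- pairs$ref_idx
    for (k in seq_along(ci)) {
      i <- ci[k]; j <- ri[k]
      if (call_active[i] && !used_call[i] && !used_ref[j]) {
        used_call[i] <- TRUE; used_ref[j] <- TRUE
        keep <- c(keep, k)
      }
    }
  }
  list(pairs = pairs[keep, ], tp = length(keep))
}

#' Precision, recall and F-score from a match result
#'
#' Recall `R = TP / (TP + FN)`, precision `P = TP / (TP + FP)`, and their
#' harmonic mean `F = 2RP / (R + P)` (0 when both are 0). A ratio with a
#' zero denominator is reported as `NA`.
#'
#' @param m a `match_result` from [match_calls()], or a list with `tp`,
#'   `fp`, `fn`.
#' @return One-row tibble with `recall`, `precision`, `f_score`.
#' @export
precision_recall_fscore <- function(m) {
  if (m$tp + m$fn == 0 && m$tp + m$fp == 0) {
    abort("No references and no calls: performance undefined.")
  }
  r <- if (m$tp + m$fn > 0) m$tp / (m$tp + m$fn) else NA_real_
  p <- if (m$tp + m$fp > 0) m$tp / (m$tp + m$fp) else NA_real_
  f <- if (is.na(r) || is.na(p)) NA_real_
       else if (r + p == 0) 0 else 2 * r * p / (r + p)
  tibble(recall = r, precision = p, f_score = f)
}

#' Area under the precision-recall curve
#'
#' Connects the deduplicated PR points sorted by recall and extrapolates the
#' polygon to both axes: a horizontal segment from (0, P) to the
#' lowest-recall point, and a closing segment from the highest-recall point
#' to the corner (recall = 1, precision = 0). Precision is integrated over
#' recall by the trapezoid rule; the result is clipped to \[0, 1\]. A single
#' perfect point (1, 1) scores 1; a single point (0.5, 1) scores 0.75.
#'
#' @param points tibble with `recall` and `precision` columns (NA rows
#'   dropped).
#' @return PR-AUC in \[0, 1\].
#' @export
pr_auc <- function(points) {
  pts <- dplyr::distinct(tibble(recall = points$recall,
                                precision = points$precision))
  pts <- pts[stats::complete.cases(pts), ]
  if (nrow(pts) == 0L) abort("No finite PR points.")
  pts <- pts[order(pts$recall, -pts$precision), ]
  r <- c(0, pts$recall, 1)
  p <- c(pts$precision[1L], pts$precision, 0)
  auc <- sum(diff(r) * (head(p, -1) + tail(p, -1)) / 2)
  min(max(auc, 0), 1)
}

#' Signal-to-noise ratio of a simulated image
#'
#' Mean spot amplitude over the standard deviation of the background.
#'
#' @param mean_amplitude mean injected spot amplitude (a.u.).
#' @param background_sd background noise SD (a.u.), > 0.
#' @return The ratio.
#' @export
snr <- function(mean_amplitude, background_sd) {
  if (background_sd <= 0) abort("`background_sd` must be positive.")
  mean_amplitude / background_sd
}

#' Spot density proxy
#'
#' Average number of spots per 9 x 9 x 5 voxel box:
#' `total_spots / ((W / 9) * (H / 9) * (D / 5))` with real-valued divisions.
#'
#' @param total_spots spot count.
#' @param W,H,D stack dimensions (voxels).
#' @return Spots per box.
#' @export
spot_density <- function(total_spots, W, H, D) {
  if (W <= 0 || H <= 0 || D <= 0) abort("Dimensions must be positive.")
  total_spots / ((W / 9) * (H / 9) * (D / 5))
}

#' Drop calls within a border region
#'
#' Keeps rows whose x and y lie at least `margin` pixels inside the frame;
#' used with the 7-pixel xy edge trim applied to simulated images before
#' performance quantification.
#'
#' @param calls call table with `x`, `y`.
#' @param W,H frame width and height.
#' @param margin border width (pixels).
#' @return The filtered call table.
#' @export
trim_xy_border <- function(calls, W, H, margin = 7) {
  dplyr::filter(calls, .data$x > margin, .data$x <= W - margin,
                .data$y > margin, .data$y <= H - margin)
}

#' Precision-recall sweep of a detection result against a reference
#'
#' Evaluates matching at every threshold of the scan: the call set at
#' threshold t is the base maxima with filtered intensity >= t, and each
#' threshold is matched greedily against the reference. Candidate pairs are
#' computed once from the base call set, which makes the sweep fast and
#' exactly equivalent to re-matching the per-threshold call subsets.
#'
#' @param det a `spot_detection` from [detect_spots()].
#' @param ref reference call table (`x`, `y`, `z`).
#' @param dims `c(W, H, D)` of the stack; when supplied with
#'   `trim_margin > 0`, both calls and references are border-trimmed first.
#' @param trim_margin xy border trim in pixels (default 0 = no trim).
#' @param max_xy,max_z matching tolerances.
#' @return A `pr_sweep`: tibble with `threshold`, `n_calls`, `tp`, `fp`,
#'   `fn`, `recall`, `precision`, `f_score`.
#' @export
pr_sweep <- function(det, ref, dims = NULL, trim_margin = 0,
                     max_xy = 4, max_z = 2) {
  calls <- det$calls
  if (trim_margin > 0) {
    if (is.null(dims)) abort("`dims` needed for border trimming.")
    calls <- trim_xy_border(calls, dims[[1L]], dims[[2L]], trim_margin)
    ref <- trim_xy_border(ref, dims[[1L]], dims[[2L]], trim_margin)
  }
  th <- det$curve$threshold
  nr <- nrow(ref)
  pairs <- candidate_pairs(calls, ref, max_xy, max_z)
  int_sorted <- sort(calls$intensity)
  res <- lapply(th, function(t) {
    active <- calls$intensity >= t
    n_calls <- length(int_sorted) - findInterval(t - 1e-9, int_sorted)
    m <- greedy_match(pairs, active, nrow(calls), nr)
    tibble(threshold = t, n_calls = n_calls, tp = m$tp,
           fp = n_calls - m$tp, fn = nr - m$tp)
  })
  out <- bind_rows(res)
  out$recall <- ifelse(out$tp + out$fn > 0, out$tp / (out$tp + out$fn), NA_real_)
  out$precision <- ifelse(out$n_calls > 0, out$tp / out$n_calls, NA_real_)
  rp <- out$recall + out$precision
  out$f_score <- ifelse(is.na(rp), NA_real_,
                        ifelse(rp == 0, 0, 2 * out$recall * out$precision / rp))
  structure(out, class = c("pr_sweep", class(tibble())))
}

#' Benchmark the detector on a batch of simulated stacks
#'
#' Generates one synthetic stack per seed (spot count drawn uniformly from
#' `n_spots_range` with a seed-derived RNG stream), runs preprocessing,
#' detection and the threshold sweep, and scores each image against its
#' ground truth with the standard matching rule (xy tolerance 4, z
#' tolerance 2) after a 7-pixel xy border trim. Images whose zero-voxel
#' proportion reaches the quality cutoff are flagged and excluded from
#' batch summaries.
#'
#' @param seeds integer vector; one simulated image per seed.
#' @param dims,bg_level,bg_sd,sigma_xy,sigma_z simulation parameters
#'   ([sim_params()]).
#' @param n_spots_range inclusive range the per-image spot count is drawn
#'   from.
#' @param amp_range spot amplitude range (a.u.), drawn uniformly per spot.
#' @param preset threshold-selection preset.
#' @return Tibble with one row per image: `seed`, `n_spots`, `zvp`,
#'   `zvp_flagged`, `selected`, `pr_auc`, `f_at_selected`, `max_recall`,
#'   `best_f`.
#' @export
benchmark_simulated_batch <- function(seeds = 1:40,
                                      dims = c(512L, 512L, 16L),
                                      n_spots_range = c(50L, 300L),
                                      amp_range = c(400, 1000),
                                      bg_level = 500, bg_sd = 50,
                                      sigma_xy = 1.3, sigma_z = 0.9,
                                      preset = "default") {
  amp_mean <- mean(amp_range)
  amp_rel_var <- (amp_range[2L] - amp_mean) / amp_mean
  rows <- lapply(seeds, function(s) {
    set.seed(s + 10^6)
    n_spots <- sample(seq(n_spots_range[1L], n_spots_range[2L]), 1L)
    p <- sim_params(dims = dims, n_spots = n_spots, amp_mean = amp_mean,
                    amp_rel_var = amp_rel_var, sigma_xy = sigma_xy,
                    sigma_z = sigma_z, bg_level = bg_level, bg_sd = bg_sd,
                    seed = s)
    sim <- simulate_stack(p)
    det <- detect_spots(sim$stack)
    sw <- pr_sweep(det, sim$truth, dims = stack_dim(sim$stack),
                   trim_margin = 7)
    thr <- tryCatch(select_threshold(det$curve, preset = preset),
                    error = function(e) NULL)
    sel <- if (is.null(thr)) NA_integer_ else thr$selected
    f_sel <- if (is.na(sel)) NA_real_ else {
      i <- which(sw$threshold == sel)
      if (length(i) == 1L) sw$f_score[i] else NA_real_
    }
    g <- glance(sw)
    tibble(seed = s, n_spots = n_spots, zvp = det$zvp,
           zvp_flagged = det$zvp_flagged, selected = sel,
           pr_auc = g$pr_auc, f_at_selected = f_sel,
           max_recall = g$max_recall, best_f = g$best_f)
  })
  bind_rows(rows)
}
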