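#' Run the detection / thresholding / quantification pipeline on a batch
#'
#' Each input (an [image_stack()] or a TIFF path) is preprocessed, run
#' through LoG detection, an intensity threshold is selected automatically
#' (or a fixed override applied), and — when requested — the retained spots
#' are Gaussian-fitted and assigned to cells. Per-image failures emit a
#' warning and are skipped in batch mode; an error is raised only when every
#' input fails.
#'
#' @param inputs list of [image_stack()] objects and/or TIFF paths.
#' @param channel channel index for multi-channel files.
#' @param scan optional [scan_range()] override.
#' @param preset threshold-selection preset ([select_threshold()]).
#' @param fixed_threshold optional fixed threshold (a.u.); skips the
#'   selection stage (used e.g. with batch-mean fixed-threshold analyses).
#' @param cells optional cell label mask (shared across the batch) for
#'   per-cell counting.
#' @param cutoff ON-cell cutoff passed to [count_per_cell()].
#' @param fit fit retained spots with [fit_spots()] (slower).
#' @param ... further arguments to [detect_spots()].
#' @return A `pipeline_result`: list with `images` (per-image result lists:
#'   `detection`, `threshold`, `spots`, `cells`), `summary` tibble (one row
#'   per image: n spots at selected threshold, selected threshold, pool
#'   stats, ZVP), and `batch` ([batch_threshold_stats()] output when at
#'   least two images succeeded and auto-thresholding was used).
#' @export
run_pipeline <- function(inputs, channel = NULL, scan = NULL,
                         preset = "default", fixed_threshold = NULL,
                         cells = NULL, cutoff = 2L, fit = FALSE, ...) {
  if (!is.list(inputs) || is_image_stack(inputs)) inputs <- list(inputs)
  results <- vector("list", length(inputs))
  rows <- vector("list", length(inputs))
  for (i in seq_along(inputs)) {
    res <- tryCatch({
      stack <- inputs[[i]]
      if (is.character(stack)) stack <- read_stack(stack, channel = channel)
      stack <- as_image_stack(stack)
      det <- detect_spots(stack, scan = scan, ...)
      thr <- NULL
      sel <- fixed_threshold
      if (is.null(sel)) {
        thr <- select_threshold(det$curve, preset = preset)
        sel <- thr$selected
      }
      retained <- dplyr::filter(det$calls, .data$intensity >= sel)
      spots <- if (fit) fit_spots(stack, retained) else NULL
      cell_tab <- if (!is.null(cells)) {
        count_per_cell(retained, cells, cutoff = cutoff)
      } else NULL
      list(detection = det, threshold = thr, selected = sel,
           retained = retained, spots = spots, cells = cell_tab)
    }, error = function(e) {
      warn(sprintf("Input %d failed: %s", i, conditionMessage(e)))
      NULL
    })
    results[[i]] <- res
    if (!is.null(res)) {
      rows[[i]] <- tibble(
        image = i, selected = res$selected, n_spots = nrow(res$retained),
        pool_mean = if (!is.null(res$threshold)) res$threshold$pool_mean else NA_real_,
        pool_sd = if (!is.null(res$threshold)) res$threshold$pool_sd else NA_real_,
        zvp = res$detection$zvp)
    }
  }
  ok <- !vapply(results, is.null, logical(1L))
  if (!any(ok)) abort("All pipeline inputs failed.")
  summary <- bind_rows(rows)
  batch <- if (sum(ok) >= 2L && is.null(fixed_threshold)) {
    batch_threshold_stats(summary$selected)
  } else NULL
  structure(list(images = results, summary = summary, batch = batch),
            class = "pipeline_result")
}

#' Batch threshold statistics
#'
#' Mean, coefficient of variation (SD / mean) and batch-mean-normalized
#' thresholds for a batch of automatically selected thresholds. The batch
#' mean is also the paper-style fixed threshold for re-running the batch.
#'
#' @param thresholds numeric vector of selected thresholds (length >= 2).
#' @return List with `mean`, `cv`, `normalized`.
#' @export
batch_threshold_stats <- function(thresholds) {
  if (length(thresholds) < 2L) abort("Need at least 2 thresholds.")
  m <- mean(thresholds)
  if (m == 0) abort("Batch mean threshold is zero.")
  list(mean = m, cv = sd(thresholds) / m, normalized = thresholds / m)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d/%d images succeeded\n",
              nrow(x$summary), length(x$images)))
  if (!is.null(x$batch)) {
    cat(sprintf("  batch threshold mean %.1f, CV %.3f\n",
                x$batch$mean, x$batch$cv))
  }
  invisible(x)
}
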