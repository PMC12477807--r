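#' Plot a spot count curve
#'
#' Spot count against intensity threshold, optionally on a log10 count
#' scale (the projection on which the elbow/plateau structure is easiest to
#' read), with the selected threshold and candidate pool overlaid when a
#' `threshold_result` is supplied.
#'
#' @param object a `spot_count_curve`.
#' @param threshold optional `threshold_result` from [select_threshold()].
#' @param log10_counts plot `log10(count + 1)`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.spot_count_curve <- function(object, threshold = NULL,
                                      log10_counts = TRUE, ...) {
  df <- tibble(threshold = object$threshold,
               count = if (log10_counts) log10(object$count + 1)
                       else as.double(object$count))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$count)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Intensity threshold (a.u.)",
                  y = if (log10_counts) "log10(spot count + 1)" else "Spot count")
  if (!is.null(threshold)) {
    p <- p +
      ggplot2::annotate("rect",
                        xmin = threshold$pool_mean - threshold$pool_sd,
                        xmax = threshold$pool_mean + threshold$pool_sd,
                        ymin = -Inf, ymax = Inf, alpha = 0.15) +
      ggplot2::geom_vline(xintercept = c(threshold$pool_min, threshold$pool_max),
                          linetype = "dotted") +
      ggplot2::geom_vline(xintercept = threshold$selected, linetype = "dashed")
  }
  p
}

#' @export
plot.spot_count_curve <- function(x, ...) print(autoplot.spot_count_curve(x, ...))

#' Plot a precision-recall sweep
#'
#' @param object a `pr_sweep` from [pr_sweep()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.pr_sweep <- function(object, ...) {
  df <- object[stats::complete.cases(object[, c("recall", "precision")]), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision")
}

#' Plot the candidate pool of a threshold selection
#'
#' @param object a `threshold_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.threshold_result <- function(object, ...) {
  ggplot2::ggplot(object$pool,
                  ggplot2::aes(x = .data$threshold, y = .data$source)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = object$selected, linetype = "dashed") +
    ggplot2::labs(x = "Candidate threshold (a.u.)", y = NULL,
                  title = sprintf("Selected %d (preset %s)",
                                  object$selected, object$preset))
}

#' Summaries of PR sweeps
#'
#' `glance()` condenses a [pr_sweep()] into the benchmarking headline
#' numbers: PR-AUC, best F-score, maximum recall.
#'
#' @param x a `pr_sweep`.
#' @param ... unused.
#' @return One-row tibble.
#' @export
glance.pr_sweep <- function(x, ...) {
  tibble(pr_auc = pr_auc(x),
         best_f = max(x$f_score, na.rm = TRUE),
         best_f_threshold = x$threshold[which.max(x$f_score)],
         max_recall = max(x$recall, na.rm = TRUE),
         n_thresholds = nrow(x))
}
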