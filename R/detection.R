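#' Suggest the intensity-threshold scan range
#'
#' The default scan minimum is 10 a.u., lowered to 5 when the 80th
#' percentile of the filtered image falls below 10 and to 1 when it falls
#' below 5. The scan maximum is 500 a.u. unless the image is bright enough
#' that both of two data-driven candidates exceed it: `ceiling(1.1 * q)`
#' with `q` the 99.9th percentile (top 0.1% with 10% leeway) and
#' `floor(max / 10)`; the smaller of the two is used when above 500.
#'
#' @param f a `filtered_stack` from [log_filter()].
#' @param leeway multiplicative leeway on the 99.9th-percentile candidate.
#' @return A `scan_range`: list with integer `t_min`, `t_max`, `step`.
#' @export
suggest_scan_range <- function(f, leeway = 0.1) {
  v <- f$voxels
  if (length(v) == 0L || max(v) == 0) {
    warn("Filtered image is empty or all zero; using default scan range.")
    return(scan_range(1L, 500L))
  }
  q80 <- quantile(v, 0.80, names = FALSE)
  t_min <- if (q80 < 5) 1L else if (q80 < 10) 5L else 10L
  a <- ceiling((1 + leeway) * quantile(v, 0.999, names = FALSE))
  b <- floor(max(v) / 10)
  t_max <- as.integer(max(500, min(a, b)))
  scan_range(t_min, t_max)
}

#' @rdname suggest_scan_range
#' @param t_min,t_max,step integer scan bounds (a.u.) and step.
#' @export
scan_range <- function(t_min, t_max, step = 1L) {
  t_min <- as.integer(t_min); t_max <- as.integer(t_max); step <- as.integer(step)
  if (t_min < 1L || t_min > t_max || step < 1L) {
    abort("Need 1 <= t_min <= t_max and step >= 1.")
  }
  structure(list(t_min = t_min, t_max = t_max, step = step), class = "scan_range")
}

#' @export
print.scan_range <- function(x, ...) {
  cat(sprintf("<scan_range> %d..%d step %d (a.u.)\n", x$t_min, x$t_max, x$step))
  invisible(x)
}

#' Find 3D local intensity maxima in a filtered stack
#'
#' Returns every voxel with filtered intensity at or above `t_min` that is
#' greater than or equal to all of its 26 neighbors (8 neighbors for a
#' depth-1 stack) and strictly above the mean of its filtered z-slice.
#' Plateaus of equal-valued adjacent maxima are collapsed to a single call
#' at the rounded centroid of the connected component, so saturated spots
#' yield one call rather than none or many.
#'
#' @param f a `filtered_stack` from [log_filter()].
#' @param t_min minimum filtered intensity considered (a.u.).
#' @return A tibble of calls with columns `x`, `y`, `z`, `intensity`.
#' @export
find_local_maxima <- function(f, t_min = 1L) {
  v <- f$voxels
  d <- dim(v)
  H <- d[1L]; W <- d[2L]; D <- d[3L]
  means <- f$slice_means
  above <- v >= t_min & v > rep(means, each = H * W)
  cand <- which(above)
  empty <- tibble(x = integer(), y = integer(), z = integer(), intensity = double())
  if (length(cand) == 0L) return(empty)

  co <- arrayInd(cand, d)
  cy <- co[, 1L]; cx <- co[, 2L]; cz <- if (ncol(co) >= 3L) co[, 3L] else rep(1L, nrow(co))
  vals <- v[cand]

  offs <- expand.grid(dy = -1:1, dx = -1:1, dz = if (D > 1L) -1:1 else 0L)
  offs <- offs[!(offs$dy == 0L & offs$dx == 0L & offs$dz == 0L), ]

  is_max <- rep(TRUE, length(cand))
  for (k in seq_len(nrow(offs))) {
    dy <- offs$dy[k]; dx <- offs$dx[k]; dz <- offs$dz[k]
    ny <- cy + dy; nx <- cx + dx; nz <- cz + dz
    ok <- ny >= 1L & ny <= H & nx >= 1L & nx <= W & nz >= 1L & nz <= D
    sel <- which(is_max & ok)
    if (length(sel) == 0L) next
    nidx <- (nz[sel] - 1L) * (H * W) + (nx[sel] - 1L) * H + ny[sel]
    is_max[sel] <- vals[sel] >= v[nidx]
  }
  mx <- which(is_max)
  if (length(mx) == 0L) return(empty)

  # collapse plateaus: connected components of adjacent equal-valued maxima
  midx <- cand[mx]
  in_max <- array(FALSE, d); in_max[midx] <- TRUE
  comp_of <- seq_along(mx)  # union-find parents
  find_root <- function(i) { while (comp_of[i] != i) { comp_of[i] <<- comp_of[comp_of[i]]; i <- comp_of[i] }; i }
  pos_of <- integer(prod(d)); pos_of[midx] <- seq_along(mx)
  my <- cy[mx]; mxx <- cx[mx]; mz <- cz[mx]; mvals <- vals[mx]
  for (k in seq_len(nrow(offs))) {
    dy <- offs$dy[k]; dx <- offs$dx[k]; dz <- offs$dz[k]
    if (dy < 0 || (dy == 0 && dx < 0) || (dy == 0 && dx == 0 && dz < 0)) next # half the offsets suffice
    ny <- my + dy; nx <- mxx + dx; nz <- mz + dz
    ok <- ny >= 1L & ny <= H & nx >= 1L & nx <= W & nz >= 1L & nz <= D
    sel <- which(ok)
    if (length(sel) == 0L) next
    nidx <- (nz[sel] - 1L) * (H * W) + (nx[sel] - 1L) * H + ny[sel]
    link <- sel[in_max[nidx] & v[nidx] == mvals[sel]]
    if (length(link) == 0L) next
    for (i in link) {
      a <- find_root(i); b <- find_root(pos_of[(mz[i] + offs$dz[k] - 1L) * (H * W) +
                                               (mxx[i] + offs$dx[k] - 1L) * H + my[i] + offs$dy[k]])
      if (a != b) comp_of[b] <- a
    }
  }
  roots <- vapply(seq_along(mx), find_root, integer(1L))
  grp <- match(roots, unique(roots))
  out <- tibble(
    x = as.integer(round(tapply(mxx, grp, mean))),
    y = as.integer(round(tapply(my, grp, mean))),
    z = as.integer(round(tapply(mz, grp, mean))),
    intensity = as.double(tapply(mvals, grp, function(a) a[1L]))
  )
  arrange(out, .data$z, .data$y, .data$x)
}

#' Spot count versus threshold curve
#'
#' For each threshold in the scan, the retained-spot count is the number of
#' base maxima with filtered intensity at or above the threshold. Because
#' the slice-mean filter uses per-slice means fixed before any threshold is
#' applied, this fast sweep is exact: zeroing sub-threshold voxels removes
#' competitors but never creates new maxima.
#'
#' @param calls base maxima from [find_local_maxima()], with intensities.
#' @param scan a [scan_range()].
#' @return A `spot_count_curve` tibble with columns `threshold`, `count`
#'   (non-increasing).
#' @export
counts_vs_threshold <- function(calls, scan) {
  th <- seq(scan$t_min, scan$t_max, by = scan$step)
  s <- sort(calls$intensity)
  cnt <- length(s) - findInterval(th - 1e-9, s)
  structure(tibble(threshold = as.integer(th), count = as.integer(cnt)),
            class = c("spot_count_curve", class(tibble())))
}

#' Run LoG spot detection on an image stack
#'
#' Full detection stage: dead-pixel repair, conditional rescale, LoG
#' filtering, scan-range suggestion, 3D maxima extraction and the
#' spot-count-versus-threshold curve.
#'
#' @param stack an [image_stack()] (or array coercible to one).
#' @param scan optional [scan_range()] override; default auto-suggested.
#' @param clean_dead repair dead pixels first (default TRUE).
#' @param r_xy,amount LoG filter parameters.
#' @param keep_filtered retain the filtered voxel grid in the result
#'   (needed only for debugging; the slice means and ZVP are always kept).
#' @return A `spot_detection` list: `calls` (base maxima tibble), `curve`
#'   (`spot_count_curve`), `scan`, `slice_means`, `zvp`, `dead_pixels`, and
#'   optionally `filtered`.
#' @export
detect_spots <- function(stack, scan = NULL, clean_dead = TRUE,
                         r_xy = 7L, amount = 2, keep_filtered = FALSE) {
  stack <- as_image_stack(stack)
  dead <- tibble(x = integer(), y = integer())
  if (clean_dead) {
    cl <- clean_dead_pixels(stack)
    stack <- cl$stack
    dead <- cl$dead_pixels
  }
  stack <- rescale_if_low_range(stack)
  f <- log_filter(stack, r_xy = r_xy, amount = amount)
  if (is.null(scan)) scan <- suggest_scan_range(f)
  calls <- find_local_maxima(f, t_min = scan$t_min)
  curve <- counts_vs_threshold(calls, scan)
  zv <- zero_voxel_proportion(f)
  structure(list(calls = calls, curve = curve, scan = scan,
                 slice_means = f$slice_means, zvp = zv$zvp,
                 zvp_flagged = zv$flagged, dead_pixels = dead,
                 filtered = if (keep_filtered) f else NULL),
            class = "spot_detection")
}

#' @export
print.spot_detection <- function(x, ...) {
  cat(sprintf("<spot_detection> %d base maxima, scan %d..%d, ZVP %.3f%s\n",
              nrow(x$calls), x$scan$t_min, x$scan$t_max, x$zvp,
              if (x$zvp_flagged) " (flagged)" else ""))
  invisible(x)
}
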