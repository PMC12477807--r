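#' Detect and repair dead pixels
#'
#' Camera-defect positions carry near-constant extreme values in every slice
#' and would otherwise seed false spot calls. A non-border (x, y) position is
#' flagged dead when its response to the 3x3 edge-detection kernel is at
#' least the filtered slice mean plus 3 filtered-slice standard deviations in
#' at least half of the sampled z-slices. The number of sampled slices is
#' `max(6, ceiling(D / 4))`, evenly spaced including the first and last
#' slice (all slices when D < 6). Dead positions are repaired per slice by
#' the mean of their 8 in-plane neighbors.
#'
#' @param stack an [image_stack()].
#' @return List with `stack` (cleaned [image_stack()]) and `dead_pixels`
#'   (tibble with columns `x`, `y`).
#' @export
clean_dead_pixels <- function(stack) {
  stack <- as_image_stack(stack)
  v <- raw_voxels(stack)
  d <- dim(v)
  H <- d[1L]; W <- d[2L]; D <- d[3L]
  if (H < 3L || W < 3L) {
    return(list(stack = stack, dead_pixels = tibble(x = integer(), y = integer())))
  }
  n_sample <- if (D < 6L) D else max(6L, as.integer(ceiling(D / 4)))
  zs <- unique(round(seq(1L, D, length.out = min(n_sample, D))))
  ek <- edge_kernel()
  votes <- matrix(0L, H, W)
  for (z in zs) {
    f <- convolve_slice(v[, , z], ek, pad = "replicate")
    s <- stats::sd(f)
    if (s == 0) next  # featureless slice: nothing stands out
    votes <- votes + (f >= mean(f) + 3 * s)
  }
  hit <- votes >= length(zs) / 2
  hit[c(1L, H), ] <- FALSE
  hit[, c(1L, W)] <- FALSE
  idx <- which(hit, arr.ind = TRUE)
  if (nrow(idx) > 0L) {
    for (k in seq_len(nrow(idx))) {
      yy <- idx[k, 1L]; xx <- idx[k, 2L]
      for (z in seq_len(D)) {
        nb <- v[(yy - 1L):(yy + 1L), (xx - 1L):(xx + 1L), z]
        v[yy, xx, z] <- (sum(nb) - nb[2L, 2L]) / 8
      }
    }
  }
  list(stack = image_stack(v, voxel_size = attr(stack, "voxel_size")),
       dead_pixels = tibble(x = as.integer(idx[, 2L]), y = as.integer(idx[, 1L])))
}

#' Linearly rescale low-dynamic-range images
#'
#' Images whose intensity span (max - min) is below 256 are linearly
#' rescaled to the range 0-511 (rounded); all other images, including
#' constant ones, are returned unchanged. This keeps integer intensity
#' thresholds meaningful on dim inputs.
#'
#' @param stack an [image_stack()].
#' @return An [image_stack()].
#' @export
rescale_if_low_range <- function(stack) {
  stack <- as_image_stack(stack)
  v <- raw_voxels(stack)
  span <- max(v) - min(v)
  if (span >= 256 || span == 0) return(stack)
  out <- round((v - min(v)) * 511 / span)
  image_stack(out, voxel_size = attr(stack, "voxel_size"))
}

#' Laplacian-of-Gaussian band-pass filter
#'
#' Applies, to each z-slice independently: a normalized Gaussian blur
#' ([make_gaussian_kernel()], default radius 7, amount 2), then the 3x3
#' edge-detection kernel ([edge_kernel()]). A border of width `r_xy` in x
#' and y is set to zero on every slice, negative responses are floored at
#' zero, and per-slice means of the resulting filtered image (over all
#' voxels, trimmed border included) are recorded for the detector's
#' slice-mean filter.
#'
#' @param stack an [image_stack()], typically after [clean_dead_pixels()]
#'   and [rescale_if_low_range()].
#' @param r_xy Gaussian radius in x/y (pixels).
#' @param amount Gaussian width parameter.
#' @return A `filtered_stack`: list with `voxels` (array `[y, x, z]` of
#'   non-negative LoG responses), `slice_means`, `r_xy`, `amount`.
#' @export
log_filter <- function(stack, r_xy = 7L, amount = 2) {
  stack <- as_image_stack(stack)
  v <- raw_voxels(stack)
  d <- dim(v)
  H <- d[1L]; W <- d[2L]; D <- d[3L]
  if (H < 2L * r_xy + 1L || W < 2L * r_xy + 1L) {
    abort("Image is smaller than the Gaussian kernel.")
  }
  gk <- make_gaussian_kernel(r_xy, amount = amount)
  ek <- edge_kernel()
  out <- array(0, dim = d)
  for (z in seq_len(D)) {
    # replicate padding: a constant image must map to an identically zero
    # response, which zero padding would violate one pixel inside the trim
    f <- convolve_slice(convolve_slice(v[, , z], gk, pad = "replicate"),
                        ek, pad = "replicate")
    f[f < 0] <- 0
    f[seq_len(r_xy), ] <- 0
    f[(H - r_xy + 1L):H, ] <- 0
    f[, seq_len(r_xy)] <- 0
    f[, (W - r_xy + 1L):W] <- 0
    out[, , z] <- f
  }
  structure(list(voxels = out,
                 slice_means = apply(out, 3L, mean),
                 r_xy = as.integer(r_xy), amount = amount),
            class = "filtered_stack")
}

#' @export
print.filtered_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<filtered_stack> %d x %d x %d (W x H x D), LoG r_xy=%d amount=%g\n",
              d[2L], d[1L], d[3L], x$r_xy, x$amount))
  invisible(x)
}

#' Zero-voxel proportion of a filtered stack
#'
#' Fraction of voxels in the LoG-filtered image that are exactly zero; a
#' cleanliness/artificiality metric for simulated images. Stacks with a
#' proportion at or above `cutoff` (default 0.7) are flagged for exclusion
#' from benchmarking summaries.
#'
#' @param f a `filtered_stack` from [log_filter()].
#' @param cutoff flagging cutoff.
#' @return List with `zvp` (fraction in \[0, 1\]) and `flagged` (logical).
#' @export
zero_voxel_proportion <- function(f, cutoff = 0.7) {
  zvp <- mean(f$voxels == 0)
  list(zvp = zvp, flagged = zvp >= cutoff)
}
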