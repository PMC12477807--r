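#' Fit a 3D Gaussian model to a called spot
#'
#' Crops a rectangular prism around the maximum (xy radius 4, z radius 2 by
#' default; clipped at stack edges) and least-squares fits a 2D Gaussian
#' `A * exp(-((x - x0)^2 + (y - y0)^2) / (2 a^2)) + offset` to each z-slice
#' of the crop. 3D parameters are inferred from the per-slice fits:
#' (x0, y0, sigma_xy) come from the slice with the largest fitted amplitude,
#' z0 is the amplitude-weighted mean slice index, and the z extent is the
#' full width at half maximum of the per-slice amplitude profile (linearly
#' interpolated). The local background is the median of the crop's in-plane
#' perimeter voxels. Non-convergent fits fall back to the raw maximum with a
#' default PSF width and are flagged.
#'
#' @param stack an [image_stack()] (raw intensities).
#' @param x,y,z integer voxel coordinates of the maximum (1-based).
#' @param r_xy,r_z crop radii (pixels / planes).
#' @param default_sigma PSF width used on fallback (pixels).
#' @return One-row tibble: `x`, `y`, `z`, `x0`, `y0`, `z0`, `amplitude`,
#'   `sigma_xy`, `z_extent`, `background`, `total_signal`, `converged`.
#' @export
fit_spot <- function(stack, x, y, z, r_xy = 4L, r_z = 2L, default_sigma = 1.5) {
  stack <- as_image_stack(stack)
  v <- raw_voxels(stack)
  d <- dim(v)
  H <- d[1L]; W <- d[2L]; D <- d[3L]
  if (x < 1 || x > W || y < 1 || y > H || z < 1 || z > D) {
    abort("Maximum lies outside the stack.")
  }
  xs <- max(1L, x - r_xy):min(W, x + r_xy)
  ys <- max(1L, y - r_xy):min(H, y + r_xy)
  zs <- max(1L, z - r_z):min(D, z + r_z)
  crop <- v[ys, xs, zs, drop = FALSE]

  # in-plane perimeter voxels of the crop, all slices
  per <- crop[c(1L, dim(crop)[1L]), , , drop = FALSE]
  per2 <- crop[, c(1L, dim(crop)[2L]), , drop = FALSE]
  b <- median(c(per, per2))

  grid <- expand.grid(yy = ys, xx = xs)
  fits <- lapply(seq_along(zs), function(k) {
    sl <- crop[, , k]
    if (max(sl) == min(sl)) return(NULL)
    df <- data.frame(xx = grid$xx, yy = grid$yy, I = as.vector(sl))
    pk <- which.max(sl)
    start <- list(A = max(sl) - min(sl),
                  x0 = grid$xx[pk], y0 = grid$yy[pk],
                  a = default_sigma, off = min(sl))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        I ~ A * exp(-((xx - x0)^2 + (yy - y0)^2) / (2 * a^2)) + off,
        data = df, start = start,
        lower = c(A = 0, x0 = min(xs) - 1, y0 = min(ys) - 1, a = 0.3,
                  off = -Inf),
        upper = c(A = Inf, x0 = max(xs) + 1, y0 = max(ys) + 1,
                  a = 2 * r_xy, off = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    cf <- coef(fit)
    if (cf[["A"]] <= 0) return(NULL)
    c(cf, z = zs[k])
  })
  fits <- fits[!vapply(fits, is.null, logical(1L))]

  if (length(fits) == 0L) {
    amp <- max(crop) - b
    out <- tibble(x = x, y = y, z = z, x0 = as.double(x), y0 = as.double(y),
                  z0 = as.double(z), amplitude = max(amp, 0),
                  sigma_xy = default_sigma, z_extent = 1,
                  background = b, total_signal = NA_real_, converged = FALSE)
  } else {
    amps <- vapply(fits, function(f) f[["A"]], double(1L))
    zz <- vapply(fits, function(f) f[["z"]], double(1L))
    best <- which.max(amps)
    z0 <- sum(amps * zz) / sum(amps)
    z_extent <- profile_fwhm(zz, amps)
    out <- tibble(x = x, y = y, z = z,
                  x0 = fits[[best]][["x0"]], y0 = fits[[best]][["y0"]],
                  z0 = z0, amplitude = amps[best],
                  sigma_xy = fits[[best]][["a"]], z_extent = z_extent,
                  background = b, total_signal = NA_real_, converged = TRUE)
  }
  out$total_signal <- integrate_signal(stack, out)
  out
}

# FWHM of a sampled profile by linear interpolation; extends to the sampled
# range edge when the half level is never crossed on a side
profile_fwhm <- function(pos, val) {
  if (length(val) == 1L) return(1)
  o <- order(pos)
  pos <- pos[o]; val <- val[o]
  pk <- which.max(val)
  half <- val[pk] / 2
  left <- pos[1L]
  if (pk > 1L) {
    for (i in pk:2L) {
      if (val[i - 1L] < half) {
        left <- pos[i - 1L] + (half - val[i - 1L]) / (val[i] - val[i - 1L]) *
          (pos[i] - pos[i - 1L])
        break
      }
    }
  }
  right <- pos[length(pos)]
  n <- length(pos)
  if (pk < n) {
    for (i in pk:(n - 1L)) {
      if (val[i + 1L] < half) {
        right <- pos[i] + (val[i] - half) / (val[i] - val[i + 1L]) *
          (pos[i + 1L] - pos[i])
        break
      }
    }
  }
  max(right - left, .Machine$double.eps)
}

#' Integrate background-subtracted signal over the fitted ellipsoid
#'
#' Sums `max(I - background, 0)` over all voxels inside the ellipsoid
#' centered at the fitted (x0, y0, z0), with xy semi-axes equal to the
#' full width at half maximum `2 * sqrt(2 * ln 2) * sigma_xy` and z
#' semi-axis `z_extent / 2` (at least 1 plane).
#'
#' @param stack an [image_stack()].
#' @param spot one-row tibble from [fit_spot()] (or any list with `x0`,
#'   `y0`, `z0`, `sigma_xy`, `z_extent`, `background`).
#' @return Integrated signal (a.u.).
#' @export
integrate_signal <- function(stack, spot) {
  v <- raw_voxels(as_image_stack(stack))
  d <- dim(v)
  rxy <- 2 * sqrt(2 * log(2)) * spot$sigma_xy
  rz <- max(spot$z_extent / 2, 1)
  xs <- max(1L, floor(spot$x0 - rxy)):min(d[2L], ceiling(spot$x0 + rxy))
  ys <- max(1L, floor(spot$y0 - rxy)):min(d[1L], ceiling(spot$y0 + rxy))
  zs <- max(1L, floor(spot$z0 - rz)):min(d[3L], ceiling(spot$z0 + rz))
  g <- expand.grid(y = ys, x = xs, z = zs)
  inside <- ((g$x - spot$x0)^2 + (g$y - spot$y0)^2) / rxy^2 +
    (g$z - spot$z0)^2 / rz^2 <= 1
  if (!any(inside)) return(0)
  idx <- (g$z[inside] - 1L) * (d[1L] * d[2L]) + (g$x[inside] - 1L) * d[1L] +
    g$y[inside]
  sum(pmax(v[idx] - spot$background, 0))
}

#' Fit all called spots in a table
#'
#' @param stack an [image_stack()].
#' @param calls call table with `x`, `y`, `z`.
#' @inheritParams fit_spot
#' @return Tibble with one [fit_spot()] row per call.
#' @export
fit_spots <- function(stack, calls, r_xy = 4L, r_z = 2L, default_sigma = 1.5) {
  bind_rows(lapply(seq_len(nrow(calls)), function(i) {
    fit_spot(stack, calls$x[i], calls$y[i], calls$z[i],
             r_xy = r_xy, r_z = r_z, default_sigma = default_sigma)
  }))
}

#' Per-cell spot counts and ON-cell flags
#'
#' Assigns each call to a cell by looking up its (x, y) — and z for 3D
#' masks — in the label mask. Calls on label 0 (outside any cell) are
#' excluded from every cell and reported in the `background_calls`
#' attribute. A cell is "ON" when its spot count reaches the channel
#' cutoff (inclusive: "at least").
#'
#' @param calls call table with `x`, `y`, `z`.
#' @param cells integer label array `[y, x]` or `[y, x, z]` (0 = outside).
#' @param nuclei optional nucleus label mask of the same shape; adds a
#'   `nuclear_count` column.
#' @param cutoff ON-cell transcript cutoff (spots per cell).
#' @return Tibble with `cell_id`, `count` (plus `nuclear_count`), `is_on`;
#'   attribute `background_calls` holds the label-0 call count.
#' @export
count_per_cell <- function(calls, cells, nuclei = NULL, cutoff = 2L) {
  md <- dim(cells)
  if (length(md) == 2L) md <- c(md, 1L)
  lab_at <- function(mask, calls) {
    d <- dim(mask)
    if (length(d) == 2L) {
      d <- c(d, 1L)
      dim(mask) <- d
    }
    zz <- if (d[3L] == 1L) rep(1L, nrow(calls)) else calls$z
    if (any(calls$x < 1 | calls$x > d[2L] | calls$y < 1 | calls$y > d[1L] |
            zz < 1 | zz > d[3L])) {
      abort("Calls fall outside the label mask; dimension mismatch.")
    }
    mask[cbind(calls$y, calls$x, zz)]
  }
  ids <- sort(setdiff(unique(as.vector(cells)), 0L))
  lab <- if (nrow(calls) > 0L) lab_at(cells, calls) else integer(0)
  counts <- table(factor(lab[lab > 0L], levels = ids))
  out <- tibble(cell_id = as.integer(ids), count = as.integer(counts))
  if (!is.null(nuclei)) {
    nlab <- if (nrow(calls) > 0L) lab_at(nuclei, calls) else integer(0)
    ncounts <- table(factor(nlab[nlab > 0L], levels = ids))
    out$nuclear_count <- as.integer(ncounts)
  }
  out$is_on <- out$count >= cutoff
  attr(out, "background_calls") <- sum(lab == 0L)
  out
}

#' ON-cell summary statistics
#'
#' @param cells tibble from [count_per_cell()].
#' @return One-row tibble: `n_cells`, `n_on`, `on_proportion`,
#'   `mean_count_among_on` (NA when no cell is ON).
#' @export
on_cell_stats <- function(cells) {
  if (nrow(cells) == 0L) abort("Empty cell list.")
  n_on <- sum(cells$is_on)
  tibble(n_cells = nrow(cells), n_on = n_on,
         on_proportion = n_on / nrow(cells),
         mean_count_among_on = if (n_on > 0) mean(cells$count[cells$is_on])
                               else NA_real_)
}

#' Derive a background mask from a transmitted-light stack
#'
#' Projects the per-(x, y) standard deviation of intensity over z — cell
#' regions vary with focus while background stays flat — then thresholds
#' the projection. When the projection's (smoothed) histogram is bimodal,
#' the local minimum between the two dominant peaks is the threshold.
#' Otherwise the projection is contrast-stretched and the threshold is
#' placed where the histogram's first-derivative approximation, after the
#' distribution peak, first shrinks below its first local-minimum value
#' divided by `C`. Background = below-threshold AND not inside any cell;
#' small holes (area < `min_hole` px) enclosed by background are filled.
#'
#' @param trans an [image_stack()] with D >= 2 (e.g. a TRANS channel).
#' @param cells integer cell label mask `[y, x]` (0 = outside).
#' @param C fallback derivative divisor.
#' @param min_hole maximum hole area to fill (pixels).
#' @param n_bins histogram bins.
#' @return Logical matrix `[y, x]`: TRUE = background.
#' @export
derive_background_mask <- function(trans, cells, C = 2, min_hole = 64L,
                                   n_bins = 128L) {
  trans <- as_image_stack(trans)
  v <- raw_voxels(trans)
  if (dim(v)[3L] < 2L) abort("Need a multi-slice stack to project over z.")
  proj <- apply(v, c(1L, 2L), stats::sd)
  thr <- histogram_valley_threshold(proj, C = C, n_bins = n_bins)
  in_cell <- cells > 0L
  if (length(dim(in_cell)) == 3L) in_cell <- apply(in_cell, c(1L, 2L), any)
  mask <- (!in_cell) & (proj < thr)
  # fill enclosed holes smaller than min_hole that contain no cell pixels
  holes <- EBImage::bwlabel(!mask)
  for (id in setdiff(unique(as.vector(holes)), 0)) {
    sel <- holes == id
    if (sum(sel) < min_hole && !any(in_cell[sel])) mask[sel] <- TRUE
  }
  mask
}

# threshold from a 1D intensity distribution: valley between two modes, or
# derivative-based fallback for unimodal distributions
histogram_valley_threshold <- function(proj, C = 2, n_bins = 128L) {
  x <- as.vector(proj)
  # bimodality on a kernel density estimate: the two dominant modes must be
  # separated by a valley dipping below half the smaller mode
  dens <- stats::density(x, n = 512L)
  dy <- dens$y
  peaks <- which(diff(sign(diff(c(-Inf, dy, -Inf)))) < 0)
  peaks <- peaks[dy[peaks] >= 0.1 * max(dy)]
  if (length(peaks) >= 2L) {
    o <- order(dy[peaks], decreasing = TRUE)
    p1 <- min(peaks[o[1:2]]); p2 <- max(peaks[o[1:2]])
    valley <- p1 + which.min(dy[p1:p2]) - 1L
    if (dy[valley] < 0.5 * min(dy[p1], dy[p2])) {
      return(dens$x[valley])
    }
  }
  # fallback for unimodal distributions: contrast-stretch, find the minimum
  # of the histogram's first-derivative approximation after the distribution
  # peak (the steepest descent of the right flank), divide that derivative
  # value by C, and threshold where the derivative magnitude first falls
  # below it — i.e. where the flank has flattened out into the tail
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1L] + 1)
  h2 <- hist((x - rng[1L]) / diff(rng), breaks = n_bins, plot = FALSE)
  cnt2 <- as.numeric(stats::filter(h2$counts, rep(1 / 15, 15), sides = 2))
  cnt2[is.na(cnt2)] <- h2$counts[is.na(cnt2)]
  pk <- which.max(cnt2)
  dd <- diff(cnt2)
  after <- if (pk <= length(dd)) pk:length(dd) else length(dd)
  lmin <- after[which.min(dd[after])]
  refv <- abs(dd[lmin]) / C
  below <- which(seq_along(dd) > lmin & abs(dd) <= refv)
  cut_bin <- if (length(below) > 0L) below[1L] else length(dd)
  rng[1L] + h2$mids[cut_bin] * diff(rng)
}
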