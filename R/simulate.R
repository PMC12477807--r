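#' Simulation parameters for synthetic FISH-like stacks
#'
#' Defaults emulate a 512 x 512 x 16 single-channel FISH stack: a flat
#' background with Gaussian read noise and diffraction-limited puncta
#' rendered as anisotropic 3D Gaussians at subpixel centers. Amplitudes
#' jitter uniformly around the mean by a relative factor; an optional
#' clustered population places extra spots around shared centers.
#'
#' @param dims `c(W, H, D)` stack dimensions (voxels).
#' @param n_spots number of isolated spots.
#' @param amp_mean mean spot amplitude (a.u. above background).
#' @param amp_rel_var relative amplitude variability: amplitudes are
#'   `amp_mean * (1 + U(-amp_rel_var, amp_rel_var))`.
#' @param sigma_xy,sigma_z PSF Gaussian widths (pixels / planes).
#' @param bg_level,bg_sd background mean and noise SD (a.u.).
#' @param n_clusters,spots_per_cluster,cluster_radius clustered population:
#'   number of cluster centers, spots per center, placement radius (px).
#' @param margin_xy xy margin (px) all spot centers stay inside.
#' @param seed RNG seed for reproducible generation.
#' @return A `sim_params` list.
#' @export
sim_params <- function(dims = c(512L, 512L, 16L), n_spots = 150L,
                       amp_mean = 700, amp_rel_var = 3 / 7,
                       sigma_xy = 1.3, sigma_z = 0.9,
                       bg_level = 500, bg_sd = 50,
                       n_clusters = 0L, spots_per_cluster = 0L,
                       cluster_radius = 5, margin_xy = 7L, seed = 1L) {
  stopifnot(length(dims) == 3L, all(dims >= 1), n_spots >= 0, bg_sd >= 0,
            amp_rel_var >= 0, n_clusters >= 0, spots_per_cluster >= 0)
  structure(list(dims = as.integer(dims), n_spots = as.integer(n_spots),
                 amp_mean = amp_mean, amp_rel_var = amp_rel_var,
                 sigma_xy = sigma_xy, sigma_z = sigma_z,
                 bg_level = bg_level, bg_sd = bg_sd,
                 n_clusters = as.integer(n_clusters),
                 spots_per_cluster = as.integer(spots_per_cluster),
                 cluster_radius = cluster_radius,
                 margin_xy = as.integer(margin_xy), seed = as.integer(seed)),
            class = "sim_params")
}

#' Simulate a synthetic FISH-like image stack with ground truth
#'
#' Background is `bg_level` plus Gaussian noise of SD `bg_sd`, clipped at
#' zero. Each spot adds an anisotropic 3D Gaussian
#' `A_i * exp(-(dx^2 + dy^2) / (2 sigma_xy^2) - dz^2 / (2 sigma_z^2))` at a
#' uniformly drawn subpixel center inside the xy margin. Output intensities
#' are quantized to integers. The same seed always yields a voxelwise
#' identical stack.
#'
#' @param p a [sim_params()] list.
#' @return List with `stack` (an [image_stack()]), `truth` (tibble `x`,
#'   `y`, `z` subpixel centers, `amplitude`, `clustered`), `params`.
#' @export
simulate_stack <- function(p) {
  W <- p$dims[1L]; H <- p$dims[2L]; D <- p$dims[3L]
  m <- p$margin_xy
  if (W - 2 * m < 1 || H - 2 * m < 1) {
    abort("Spots cannot fit inside the xy margins.")
  }
  set.seed(p$seed)
  n_cl <- p$n_clusters * p$spots_per_cluster
  n_tot <- p$n_spots + n_cl
  sx <- runif(p$n_spots, m + 1, W - m)
  sy <- runif(p$n_spots, m + 1, H - m)
  sz <- runif(p$n_spots, 1, D)
  clustered <- rep(FALSE, p$n_spots)
  if (n_cl > 0L) {
    ccx <- runif(p$n_clusters, m + 1 + p$cluster_radius, W - m - p$cluster_radius)
    ccy <- runif(p$n_clusters, m + 1 + p$cluster_radius, H - m - p$cluster_radius)
    ccz <- runif(p$n_clusters, 1, D)
    for (k in seq_len(p$n_clusters)) {
      ang <- runif(p$spots_per_cluster, 0, 2 * pi)
      rad <- p$cluster_radius * sqrt(runif(p$spots_per_cluster))
      sx <- c(sx, pmin(pmax(ccx[k] + rad * cos(ang), m + 1), W - m))
      sy <- c(sy, pmin(pmax(ccy[k] + rad * sin(ang), m + 1), H - m))
      sz <- c(sz, pmin(pmax(ccz[k] + runif(p$spots_per_cluster, -1, 1), 1), D))
      clustered <- c(clustered, rep(TRUE, p$spots_per_cluster))
    }
  }
  amp <- p$amp_mean * (1 + runif(n_tot, -p$amp_rel_var, p$amp_rel_var))

  v <- array(pmax(p$bg_level + rnorm(W * H * D, 0, p$bg_sd), 0), dim = c(H, W, D))
  rx <- ceiling(4 * p$sigma_xy)
  rz <- ceiling(4 * p$sigma_z)
  for (i in seq_len(n_tot)) {
    xs <- max(1L, floor(sx[i]) - rx):min(W, ceiling(sx[i]) + rx)
    ys <- max(1L, floor(sy[i]) - rx):min(H, ceiling(sy[i]) + rx)
    zs <- max(1L, floor(sz[i]) - rz):min(D, ceiling(sz[i]) + rz)
    gx <- exp(-(xs - sx[i])^2 / (2 * p$sigma_xy^2))
    gy <- exp(-(ys - sy[i])^2 / (2 * p$sigma_xy^2))
    gz <- exp(-(zs - sz[i])^2 / (2 * p$sigma_z^2))
    bump <- amp[i] * outer(outer(gy, gx), gz)
    v[ys, xs, zs] <- v[ys, xs, zs] + bump
  }
  v <- round(v)
  list(stack = image_stack(v),
       truth = tibble(x = sx, y = sy, z = sz, amplitude = amp,
                      clustered = clustered),
       params = p)
}

#' Diffuse-signal blur degradation
#'
#' Applies a normalized 3D Gaussian blur (default xy radius 7, z radius 2,
#' amount 4) to emulate the dull, blurry appearance of GFP-tagged protein
#' images. Total interior intensity is conserved by kernel normalization.
#'
#' @param stack an [image_stack()].
#' @param r_xy,r_z,amount kernel parameters ([make_gaussian_kernel()]).
#' @return The blurred [image_stack()].
#' @export
apply_gfp_blur <- function(stack, r_xy = 7L, r_z = 2L, amount = 4) {
  stack <- as_image_stack(stack)
  v <- raw_voxels(stack)
  D <- dim(v)[3L]
  if (D < 2L * r_z + 1L) abort("Stack is thinner than the blur kernel in z.")
  # separable: normalized 2D xy Gaussian per slice, then 1D along z
  g2 <- make_gaussian_kernel(r_xy, amount = amount)
  out <- array(0, dim = dim(v))
  for (z in seq_len(D)) out[, , z] <- convolve_slice(v[, , z], g2)
  gz <- exp(-seq(-r_z, r_z)^2 / (2 * amount^2))
  gz <- gz / sum(gz)
  res <- array(0, dim = dim(v))
  for (k in seq(-r_z, r_z)) {
    w <- gz[k + r_z + 1L]
    zsrc <- seq_len(D) - k
    ok <- zsrc >= 1L & zsrc <= D
    res[, , ok] <- res[, , ok] + w * out[, , zsrc[ok]]
  }
  image_stack(res, voxel_size = attr(stack, "voxel_size"))
}

#' Edge-darkening degradation
#'
#' Emulates uneven illumination favoring the plane center: a darkening
#' factor f drawn uniformly from \[0.01, 0.10\] scales each pixel by
#' `1 - f * dist / dist_max` (dist = distance from the plane center), with
#' up to 5% uniform multiplicative noise added to the darkening filter,
#' clipped at zero.
#'
#' @param stack an [image_stack()].
#' @param seed RNG seed.
#' @return List with `stack` and the drawn `factor`.
#' @export
apply_edge_darkening <- function(stack, seed = 1L) {
  stack <- as_image_stack(stack)
  v <- raw_voxels(stack)
  d <- dim(v)
  H <- d[1L]; W <- d[2L]; D <- d[3L]
  set.seed(seed)
  f <- runif(1, 0.01, 0.10)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  dist <- sqrt(outer((seq_len(H) - cy)^2, (seq_len(W) - cx)^2, `+`))
  dist_max <- max(dist)
  base <- 1 - f * dist / dist_max
  for (z in seq_len(D)) {
    noise <- matrix(runif(H * W, -0.05, 0.05), H, W)
    v[, , z] <- pmax(v[, , z] * base * (1 + noise), 0)
  }
  list(stack = image_stack(v, voxel_size = attr(stack, "voxel_size")),
       factor = f)
}

#' Defocus degradation
#'
#' Emulates out-of-focus z-planes near the stack extremes. A maximum
#' strength `s_max` is drawn uniformly from \[1.1, 2.5\]; each plane is
#' blended with its radius-5 Gaussian-blurred version using weight
#' `w = min(1, s(z) - 1)` where `s(z) = 1 + (s_max - 1) * |z - z_c| /
#' max|z - z_c|`. The center plane is left untouched.
#'
#' @param stack an [image_stack()] with D >= 3.
#' @param seed RNG seed.
#' @param blur_radius,blur_amount Gaussian blur kernel parameters.
#' @return List with `stack` and the drawn `max_strength`.
#' @export
apply_defocus <- function(stack, seed = 1L, blur_radius = 5L,
                          blur_amount = 2.5) {
  stack <- as_image_stack(stack)
  v <- raw_voxels(stack)
  D <- dim(v)[3L]
  if (D < 3L) abort("Need at least 3 planes for defocus scaling.")
  set.seed(seed)
  s_max <- runif(1, 1.1, 2.5)
  zc <- (D + 1) / 2
  dz <- abs(seq_len(D) - zc)
  g <- make_gaussian_kernel(blur_radius, amount = blur_amount)
  for (z in seq_len(D)) {
    w <- min(1, (1 + (s_max - 1) * dz[z] / max(dz)) - 1)
    if (w == 0) next
    v[, , z] <- (1 - w) * v[, , z] + w * convolve_slice(v[, , z], g)
  }
  list(stack = image_stack(v, voxel_size = attr(stack, "voxel_size")),
       max_strength = s_max)
}
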