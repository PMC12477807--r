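#' Normalized Gaussian convolution kernels
#'
#' Builds the separable-in-shape (but explicitly normalized) Gaussian kernel
#' used both for the Laplacian-of-Gaussian band-pass filter and for the
#' simulator's blur degradations. The 2D kernel has side lengths
#' `X = 2*r_x + 1`, `Y = 2*r_y + 1`; the 3D variant adds `Z = 2*r_z + 1`
#' planes. The unnormalized weight at offset (dx, dy[, dz]) is
#' `exp(-(dx^2 + dy^2[ + dz^2]) / (2 * amount^2))`; weights are divided by
#' their sum, so any constant leading factor cancels and the `amount`
#' parameter alone sets the width.
#'
#' @param r_xy integer radius in x and y (pixels); side length `2*r_xy + 1`.
#' @param r_z optional integer radius in z (planes); when supplied a 3D
#'   kernel is returned.
#' @param amount positive width parameter of the exponent `2*amount^2`.
#' @return A `gaussian_kernel`: numeric array of weights summing to 1, with
#'   attributes `r_xy`, `r_z`, `amount`.
#' @export
make_gaussian_kernel <- function(r_xy, r_z = NULL, amount) {
  if (r_xy < 1 || (!is.null(r_z) && r_z < 1)) abort("Kernel radii must be >= 1.")
  if (amount <= 0) abort("`amount` must be positive.")
  dx <- seq(-r_xy, r_xy)
  g1 <- exp(-dx^2 / (2 * amount^2))
  if (is.null(r_z)) {
    w <- outer(g1, g1)
  } else {
    dz <- seq(-r_z, r_z)
    gz <- exp(-dz^2 / (2 * amount^2))
    w <- outer(outer(g1, g1), gz)
  }
  w <- w / sum(w)
  structure(w, r_xy = as.integer(r_xy),
            r_z = if (is.null(r_z)) NULL else as.integer(r_z),
            amount = amount, class = c("gaussian_kernel", class(w)))
}

#' 3x3 edge-detection kernel
#'
#' The fixed Laplacian-like high-pass kernel: -1 everywhere with +8 at the
#' center, so weights sum to zero and any constant region maps to zero.
#'
#' @return A 3x3 numeric matrix.
#' @export
edge_kernel <- function() {
  k <- matrix(-1, 3L, 3L)
  k[2L, 2L] <- 8
  k
}

# 2D convolution of one slice with a centered kernel, zero padding outside.
# Separable (rank-1) kernels, e.g. Gaussians, use two 1D passes; anything
# else falls back to a direct shift-and-add accumulation.
convolve_slice <- function(slice, kernel, pad = c("zero", "replicate")) {
  pad <- match.arg(pad)
  kernel <- unclass(kernel)
  sv <- svd(kernel, nu = 1L, nv = 1L)
  if (sv$d[1L] > 0 &&
      (length(sv$d) == 1L || sv$d[2L] < 1e-12 * sv$d[1L])) {
    wy <- sv$u[, 1L] * sqrt(sv$d[1L])
    wx <- sv$v[, 1L] * sqrt(sv$d[1L])
    if (sum(wy) < 0) { wy <- -wy; wx <- -wx }
    return(conv1d_x(conv1d_y(slice, wy, pad), wx, pad))
  }
  kd <- dim(kernel)
  ry <- (kd[1L] - 1L) %/% 2L
  rx <- (kd[2L] - 1L) %/% 2L
  H <- nrow(slice); W <- ncol(slice)
  padded <- pad_matrix(slice, ry, rx, pad)
  out <- matrix(0, H, W)
  for (i in seq_len(kd[1L])) {
    for (j in seq_len(kd[2L])) {
      w <- kernel[i, j]
      if (w == 0) next
      # kernel entry at offset (i - ry - 1, j - rx - 1) from the center;
      # convolution flips the kernel
      out <- out + w * padded[(2L * ry + 2L - i):(2L * ry + 1L - i + H),
                              (2L * rx + 2L - j):(2L * rx + 1L - j + W)]
    }
  }
  out
}

pad_matrix <- function(mat, ry, rx, pad) {
  H <- nrow(mat); W <- ncol(mat)
  padded <- matrix(0, H + 2L * ry, W + 2L * rx)
  padded[(ry + 1L):(ry + H), (rx + 1L):(rx + W)] <- mat
  if (pad == "replicate") {
    if (ry > 0L) {
      padded[seq_len(ry), (rx + 1L):(rx + W)] <- mat[rep(1L, ry), , drop = FALSE]
      padded[(ry + H + 1L):(H + 2L * ry), (rx + 1L):(rx + W)] <-
        mat[rep(H, ry), , drop = FALSE]
    }
    if (rx > 0L) {
      padded[, seq_len(rx)] <- padded[, rep(rx + 1L, rx), drop = FALSE]
      padded[, (rx + W + 1L):(W + 2L * rx)] <-
        padded[, rep(rx + W, rx), drop = FALSE]
    }
  }
  padded
}

# 1D convolution along rows (y) / columns (x); `w` has odd length and is
# indexed symmetrically about its center
conv1d_y <- function(mat, w, pad = "zero") {
  r <- (length(w) - 1L) %/% 2L
  H <- nrow(mat); W <- ncol(mat)
  padded <- pad_matrix(mat, r, 0L, pad)
  out <- matrix(0, H, W)
  for (k in seq_along(w)) {
    if (w[k] == 0) next
    out <- out + w[k] * padded[(2L * r + 2L - k):(2L * r + 1L - k + H), , drop = FALSE]
  }
  out
}

conv1d_x <- function(mat, w, pad = "zero") t(conv1d_y(t(mat), w, pad))
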