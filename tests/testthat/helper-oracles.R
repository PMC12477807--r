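# Independent brute-force oracles used across the suite. These deliberately
# re-derive results with the slowest, most literal implementation possible.

# naive nested-loop 2D convolution with zero padding (true convolution:
# kernel flipped)
naive_convolve <- function(slice, kernel) {
  ry <- (nrow(kernel) - 1L) %/% 2L
  rx <- (ncol(kernel) - 1L) %/% 2L
  out <- matrix(0, nrow(slice), ncol(slice))
  for (y in seq_len(nrow(slice))) {
    for (x in seq_len(ncol(slice))) {
      s <- 0
      for (i in -ry:ry) {
        for (j in -rx:rx) {
          yy <- y - i; xx <- x - j
          if (yy >= 1 && yy <= nrow(slice) && xx >= 1 && xx <= ncol(slice)) {
            s <- s + kernel[i + ry + 1L, j + rx + 1L] * slice[yy, xx]
          }
        }
      }
      out[y, x] <- s
    }
  }
  out
}

# exhaustive 26-neighbor (8 in 2D) local maxima scan with plateau collapse,
# slice-mean filter and intensity floor — mirrors the detector's definition
# but enumerated voxel by voxel
brute_maxima <- function(v, t_min, slice_means) {
  d <- dim(v)
  is_max <- array(FALSE, d)
  for (z in seq_len(d[3L])) {
    for (x in seq_len(d[2L])) {
      for (y in seq_len(d[1L])) {
        val <- v[y, x, z]
        if (val < t_min || val <= slice_means[z]) next
        ok <- TRUE
        for (dz in -1:1) {
          for (dx in -1:1) {
            for (dy in -1:1) {
              if (dx == 0 && dy == 0 && dz == 0) next
              yy <- y + dy; xx <- x + dx; zz <- z + dz
              if (yy < 1 || yy > d[1L] || xx < 1 || xx > d[2L] ||
                  zz < 1 || zz > d[3L]) next
              if (v[yy, xx, zz] > val) ok <- FALSE
            }
          }
        }
        if (ok) is_max[y, x, z] <- TRUE
      }
    }
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(tibble::tibble(x = integer(), y = integer(), z = integer(),
                          intensity = double()))
  }
  # plateau collapse via flood fill over equal-valued adjacent maxima
  n <- nrow(idx)
  grp <- rep(NA_integer_, n)
  g <- 0L
  for (i in seq_len(n)) {
    if (!is.na(grp[i])) next
    g <- g + 1L
    queue <- i
    grp[i] <- g
    while (length(queue) > 0L) {
      cur <- queue[1L]; queue <- queue[-1L]
      for (j in seq_len(n)) {
        if (!is.na(grp[j])) next
        if (abs(idx[j, 1L] - idx[cur, 1L]) <= 1L &&
            abs(idx[j, 2L] - idx[cur, 2L]) <= 1L &&
            abs(idx[j, 3L] - idx[cur, 3L]) <= 1L &&
            v[idx[j, , drop = FALSE]] == v[idx[cur, , drop = FALSE]]) {
          grp[j] <- g
          queue <- c(queue, j)
        }
      }
    }
  }
  out <- tibble::tibble(
    x = as.integer(round(tapply(idx[, 2L], grp, mean))),
    y = as.integer(round(tapply(idx[, 1L], grp, mean))),
    z = as.integer(round(tapply(idx[, 3L], grp, mean))),
    intensity = as.double(tapply(v[idx], grp, function(a) a[1L]))
  )
  dplyr::arrange(out, z, y, x)
}

# exhaustive one-to-one assignment maximizing matched pairs, then minimizing
# total xy distance, within the (max_xy, max_z) tolerance; recursion over
# references, feasible for <= 8 points
exhaustive_match_tp <- function(calls, ref, max_xy = 4, max_z = 2) {
  nr <- nrow(ref)
  cand <- lapply(seq_len(nr), function(j) {
    d2 <- (calls$x - ref$x[j])^2 + (calls$y - ref$y[j])^2
    ok <- which(d2 <= max_xy^2 & abs(calls$z - ref$z[j]) <= max_z)
    list(idx = ok, dist = sqrt(d2[ok]))
  })
  best <- c(tp = 0, dist = Inf)
  recurse <- function(j, used, tp, dist) {
    if (j > nr) {
      if (tp > best[["tp"]] ||
          (tp == best[["tp"]] && dist < best[["dist"]])) {
        best <<- c(tp = tp, dist = dist)
      }
      return(invisible())
    }
    recurse(j + 1L, used, tp, dist)  # leave ref j unmatched
    for (k in seq_along(cand[[j]]$idx)) {
      i <- cand[[j]]$idx[k]
      if (!used[i]) {
        used[i] <- TRUE
        recurse(j + 1L, used, tp + 1L, dist + cand[[j]]$dist[k])
        used[i] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, nrow(calls)), 0L, 0)
  best[["tp"]]
}

# construct a filtered_stack directly from a voxel array (for detector tests
# that bypass the LoG filter)
fake_filtered <- function(v) {
  if (length(dim(v)) == 2L) dim(v) <- c(dim(v), 1L)
  structure(list(voxels = v, slice_means = apply(v, 3L, mean),
                 r_xy = 0L, amount = NA_real_),
            class = "filtered_stack")
}

# inject an anisotropic 3D Gaussian spot into an array (simulator-independent)
inject_spot <- function(v, x0, y0, z0, A, sigma_xy, sigma_z) {
  d <- dim(v)
  for (z in seq_len(d[3L])) {
    gz <- exp(-(z - z0)^2 / (2 * sigma_z^2))
    if (gz < 1e-8) next
    gx <- exp(-(seq_len(d[2L]) - x0)^2 / (2 * sigma_xy^2))
    gy <- exp(-(seq_len(d[1L]) - y0)^2 / (2 * sigma_xy^2))
    v[, , z] <- v[, , z] + A * gz * outer(gy, gx)
  }
  v
}

# archetypal spot count curves built by construction
curve_high_expression <- function() {
  th <- 1:300
  counts <- round(20000 * exp(-th / 4)) +
    ifelse(th <= 150, 200L, round(200 * exp(-(th - 150) / 4)))
  tibble::tibble(threshold = th, count = as.integer(counts))
}

curve_low_expression <- function() {
  th <- 1:300
  counts <- round(5000 * exp(-th / 4) + 20 * exp(-th / 400))
  tibble::tibble(threshold = th, count = as.integer(counts))
}

curve_variable_intensity <- function() {
  th <- 1:300
  counts <- round(50000 * th^-1.8)
  tibble::tibble(threshold = th, count = as.integer(counts))
}
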