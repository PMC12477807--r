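#' Image stacks
#'
#' An `image_stack` is a 3D numeric array of non-negative intensities in
#' arbitrary units, stored as `[y, x, z]` (row = y, column = x, slice = z),
#' the native orientation of raster files read by [tiff::readTIFF()]. A 2D
#' image is simply a stack of depth 1; every operation in the package accepts
#' both. An optional `voxel_size` attribute carries the physical spacing per
#' axis in nanometres, named `c(x, y, z)`.
#'
#' All voxel coordinates in call tables are 1-based integers with columns
#' `x` (1..width), `y` (1..height), `z` (1..depth).
#'
#' @param voxels numeric matrix or 3D array of finite, non-negative
#'   intensities.
#' @param voxel_size optional named numeric vector `c(x=, y=, z=)`, physical
#'   spacing in nm.
#' @return An `image_stack` (3D array with class attribute).
#' @export
image_stack <- function(voxels, voxel_size = NULL) {
  if (is.matrix(voxels)) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 3L) {
    abort("`voxels` must be a matrix or a 3D array.")
  }
  if (!all(is.finite(voxels)) || any(voxels < 0)) {
    abort("All intensities must be finite and non-negative.")
  }
  storage.mode(voxels) <- "double"
  structure(voxels, voxel_size = voxel_size, class = "image_stack")
}

#' @rdname image_stack
#' @param x object to coerce or test.
#' @export
as_image_stack <- function(x) {
  if (is_image_stack(x)) x else image_stack(x)
}

#' @rdname image_stack
#' @export
is_image_stack <- function(x) inherits(x, "image_stack")

#' @export
print.image_stack <- function(x, ...) {
  d <- stack_dim(x)
  cat(sprintf("<image_stack> %d x %d x %d (W x H x D), range [%g, %g]\n",
              d[["W"]], d[["H"]], d[["D"]], min(x), max(x)))
  invisible(x)
}

#' Dimensions of a stack as width/height/depth
#'
#' @param stack an `image_stack` or plain array.
#' @return Named integer vector `c(W, H, D)`.
#' @export
stack_dim <- function(stack) {
  d <- dim(stack)
  if (is.null(d)) abort("Not an image stack.")
  if (length(d) == 2L) d <- c(d, 1L)
  c(W = d[2L], H = d[1L], D = d[3L])
}

# strip class for fast arithmetic
raw_voxels <- function(stack) {
  v <- unclass(stack)
  attr(v, "voxel_size") <- NULL
  v
}

#' Read an image stack from a (multi-page) TIFF file
#'
#' Pages are mapped to z in file order. Multi-sample (multi-channel) pages
#' require an explicit `channel`; no channel is ever guessed.
#'
#' @param path path to a single- or multi-page TIFF.
#' @param channel 1-based channel index for multi-channel pages; may be
#'   omitted for single-channel files.
#' @return An [image_stack()] with intensities preserved bit-exactly.
#' @export
read_stack <- function(path, channel = NULL) {
  if (!file.exists(path)) abort(sprintf("Cannot read image file '%s'.", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  n_chan <- if (length(dim(pages[[1L]])) == 3L) dim(pages[[1L]])[3L] else 1L
  if (n_chan > 1L && is.null(channel)) {
    abort(sprintf("File has %d channels; select one explicitly (available: %s).",
                  n_chan, paste(seq_len(n_chan), collapse = ", ")))
  }
  if (is.null(channel)) channel <- 1L
  if (channel < 1L || channel > n_chan) {
    abort(sprintf("Channel %d out of range; available channels: %s.",
                  channel, paste(seq_len(n_chan), collapse = ", ")))
  }
  slices <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p[, , channel] else p
  })
  v <- array(0, dim = c(dim(slices[[1L]]), length(slices)))
  for (k in seq_along(slices)) v[, , k] <- slices[[k]]
  image_stack(v)
}

#' Write an image stack to a multi-page TIFF file
#'
#' Intensities are stored as unsigned integers; the round trip through
#' [read_stack()] is voxelwise exact for integer intensities within range.
#'
#' @param stack an [image_stack()].
#' @param path output path.
#' @param bits bits per sample (8, 16 or 32).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  stack <- as_image_stack(stack)
  if (!bits %in% c(8L, 16L, 32L)) abort("`bits` must be 8, 16 or 32.")
  top <- 2^bits - 1
  if (max(stack) > top) {
    abort(sprintf("Intensities exceed %d; use more bits per sample.", top))
  }
  v <- raw_voxels(stack)
  pages <- lapply(seq_len(dim(v)[3L]), function(k) v[, , k] / top)
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Read a label mask (cell/nucleus segmentation) from TIFF
#'
#' Labels are non-negative integers: 0 marks positions outside any cell,
#' k > 0 a cell id. A single-page mask is applied to every slice of a
#' matching stack; a multi-page mask must match the stack's depth.
#'
#' @param path path to a label-image TIFF.
#' @return Integer array `[y, x, z]` of labels.
#' @export
read_label_mask <- function(path) {
  m <- raw_voxels(read_stack(path))
  storage.mode(m) <- "integer"
  if (any(m < 0)) abort("Label masks must be non-negative integers.")
  m
}

#' Maximum intensity projection over z
#'
#' Collapses a stack to depth 1 by taking, at every (x, y) position, the
#' maximum intensity across the selected z-slices.
#'
#' @param stack an [image_stack()].
#' @param z_range optional inclusive `c(lo, hi)` slice interval; default all
#'   slices.
#' @return A depth-1 [image_stack()].
#' @export
max_intensity_projection <- function(stack, z_range = NULL) {
  stack <- as_image_stack(stack)
  v <- raw_voxels(stack)
  D <- dim(v)[3L]
  if (is.null(z_range)) z_range <- c(1L, D)
  if (length(z_range) != 2L || z_range[1L] > z_range[2L] ||
      z_range[1L] < 1L || z_range[2L] > D) {
    abort(sprintf("`z_range` must be an inclusive interval within [1, %d].", D))
  }
  sel <- v[, , z_range[1L]:z_range[2L], drop = FALSE]
  mip <- apply(sel, c(1L, 2L), max)
  image_stack(mip, voxel_size = attr(stack, "voxel_size"))
}

#' Trim a reference call table to a z-slice window
#'
#' When a projection or analysis is derived from a trimmed range of z-slices,
#' reference calls farther than 2 z-slices outside the trim edges are
#' removed; calls within 2 slices of either edge are retained (inclusive).
#'
#' @param calls a call table (tibble with at least a `z` column).
#' @param z_lo,z_hi inclusive trim interval.
#' @return The filtered call table.
#' @export
trim_reference_to_z <- function(calls, z_lo, z_hi) {
  if (z_lo > z_hi) abort("`z_lo` must not exceed `z_hi`.")
  dplyr::filter(calls, .data$z >= z_lo - 2, .data$z <= z_hi + 2)
}

#' Read and write spot call tables
#'
#' Call tables are CSVs with header `x,y,z,intensity` plus optional
#' `threshold` and `cell_id` columns. Coordinates are 1-based voxel indices;
#' a `# coord_base=1` comment line records the convention on export and
#' comment lines are skipped on import.
#'
#' @param calls tibble of calls.
#' @param path CSV path.
#' @return `read_calls()`: a tibble; `write_calls()`: `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coord_base=1", con)
  write.csv(as.data.frame(calls), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  df <- read.csv(path, comment.char = "#")
  if (!all(c("x", "y", "z") %in% names(df))) {
    abort("Call table must have columns x, y, z.")
  }
  as_tibble(df)
}
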