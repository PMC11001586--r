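#' Construct a channel stack
#'
#' A channel stack is a 3D array of nonnegative intensities indexed
#' `[row, col, slice]`, carrying a channel label and bit depth. A matrix
#' is promoted to a single-slice stack.
#'
#' @param voxels Numeric matrix or 3D array of nonnegative intensities.
#' @param channel_label Channel name, e.g. `"405"`, `"488"`, `"green"`.
#' @param bit_depth 8 or 16; metadata used when writing TIFF.
#' @return An object of class `channel_stack` (a 3D array with attributes).
#' @export
channel_stack <- function(voxels, channel_label = "ch", bit_depth = 16) {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(dim(voxels), 1L))
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a matrix or 3D array [row, col, slice]")
  if (anyNA(voxels) || any(voxels < 0)) stop("intensities must be nonnegative")
  if (!bit_depth %in% c(8, 16)) stop("bit_depth must be 8 or 16")
  structure(voxels, channel_label = as.character(channel_label),
            bit_depth = as.integer(bit_depth), class = c("channel_stack", "array"))
}

as_stack_array <- function(x) {
  if (inherits(x, "channel_stack")) return(unclass(x))
  if (is.matrix(x)) return(array(x, dim = c(dim(x), 1L)))
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stop("expected a channel_stack, matrix or 3D array")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<channel_stack> '%s': %d x %d x %d slices, %d-bit, range [%g, %g]\n",
              attr(x, "channel_label"), d[1], d[2], d[3],
              attr(x, "bit_depth"), min(x), max(x)))
  invisible(x)
}

#' Read a multi-page TIFF as a channel stack
#'
#' @param path TIFF file path.
#' @param channel_label Label to attach to the stack.
#' @return A [channel_stack()]. Intensities are rescaled from the [0, 1]
#'   convention of [tiff::readTIFF()] back to integer counts.
#' @export
read_stack <- function(path, channel_label = "ch") {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bps <- attr(pages[[1L]], "bits.per.sample")
  if (is.null(bps)) bps <- 16L
  scale <- 2^bps - 1
  arr <- vapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # first plane of RGB pages
    round(p * scale)
  }, matrix(0, nrow(pages[[1L]]), ncol(pages[[1L]])))
  channel_stack(array(arr, dim = c(dim(pages[[1L]])[1:2], length(pages))),
                channel_label = channel_label, bit_depth = bps)
}

#' Write a channel stack to a multi-page TIFF
#'
#' @param stack A [channel_stack()] or 3D array of integer intensities.
#' @param path Output path.
#' @param bit_depth 8 or 16; intensities must fit the depth.
#' @export
write_stack <- function(stack, path, bit_depth = NULL) {
  arr <- as_stack_array(stack)
  if (is.null(bit_depth))
    bit_depth <- if (!is.null(attr(stack, "bit_depth"))) attr(stack, "bit_depth") else 16L
  scale <- 2^bit_depth - 1
  if (max(arr) > scale) stop("intensities exceed the requested bit depth")
  pages <- lapply(seq_len(dim(arr)[3L]), function(z) arr[, , z] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bit_depth)
  invisible(path)
}

#' Apply an exclusion mask to a stack
#'
#' Nonzero mask pixels mark debris/non-brain regions to exclude from
#' analysis; they are set to `NA`. A 2D mask is recycled over slices.
#'
#' @param stack A stack or array.
#' @param mask Logical/numeric matrix or array; nonzero or TRUE = exclude.
#' @return The array with excluded voxels set to `NA`.
#' @export
apply_exclusion_mask <- function(stack, mask) {
  arr <- as_stack_array(stack)
  if (is.null(mask)) return(arr)
  m <- as_stack_array(mask) != 0
  if (dim(m)[3L] == 1L && dim(arr)[3L] > 1L)
    m <- array(m[, , 1L], dim = dim(arr))
  if (!all(dim(m) == dim(arr))) stop("mask shape must match the stack")
  arr[m] <- NA
  arr
}
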