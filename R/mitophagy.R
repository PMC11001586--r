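#' Colocalization window configuration
#'
#' @param n_slices Number of z slices analyzed per brain (default 30,
#'   held constant across brains so indices are comparable).
#' @param start_mode `"max_mito_area"`: start at the slice with the
#'   greatest mitochondrial signal area (used for surface-weighted glial
#'   signal); `"first_slice"`: start at slice 1 (full-stack analyses).
#' @param binarization Optional [segmentation_config()] used when raw
#'   intensity stacks are supplied; defaults to per-slice Renyi-entropy
#'   thresholding.
#' @return An object of class `coloc_config`.
#' @export
coloc_config <- function(n_slices = 30, start_mode = c("max_mito_area", "first_slice"),
                         binarization = NULL) {
  start_mode <- match.arg(start_mode)
  if (n_slices < 1) stop("n_slices must be >= 1")
  if (is.null(binarization))
    binarization <- segmentation_config(method = "renyi", mode = "per_slice")
  structure(list(n_slices = as.integer(n_slices), start_mode = start_mode,
                 binarization = binarization),
            class = "coloc_config")
}

#' Select the starting slice of the analysis window
#'
#' In `max_mito_area` mode, returns the slice with the greatest
#' mitochondrial foreground area (ties break to the lowest index); in
#' `first_slice` mode, returns 1.
#'
#' @param mito_binary Binarized mitochondrial stack (logical/0-1 array).
#' @param config A [coloc_config()].
#' @return 1-based slice index.
#' @export
select_window <- function(mito_binary, config = coloc_config()) {
  arr <- as_stack_array(mito_binary)
  if (length(arr) == 0L || dim(arr)[3L] < 1L) stop("empty stack")
  if (config$start_mode == "first_slice") return(1L)
  areas <- apply(arr != 0, 3L, sum)
  which.max(areas)  # first max on ties
}

#' Mitophagy colocalization index
#'
#' For each z slice in the analysis window, the colocalized area (pixels
#' positive in both the mitochondrial and autophagosome masks) is
#' normalized to the mitochondrial area of that slice; the index is the
#' sum of these per-slice ratios over the window. Slices with zero
#' mitochondrial area contribute 0, keeping the index in
#' `[0, n_slices]`. When fewer than `n_slices` slices remain after the
#' starting slice, the window is clipped with a warning.
#'
#' Downstream normalization to a reference-group mean (e.g. the ZT0
#' group) uses [normalize_to_group_mean()].
#'
#' @param mito_binary,atg_binary Binarized stacks of equal shape
#'   (mitochondria; autophagosomes). Raw intensity stacks are binarized
#'   with `config$binarization` when `binarized = FALSE`.
#' @param config A [coloc_config()].
#' @param binarized Set to `FALSE` to auto-threshold raw stacks first.
#' @return Object of class `mitophagy_result`: `index`,
#'   `per_slice_ratio`, `window_start`, `n_slices_used`, `clipped`.
#' @export
coloc_index <- function(mito_binary, atg_binary, config = coloc_config(),
                        binarized = TRUE) {
  mito <- as_stack_array(mito_binary)
  atg <- as_stack_array(atg_binary)
  if (!all(dim(mito) == dim(atg))) stop("mito and autophagosome stacks must share shape")
  if (!binarized) {
    mito <- unclass(segment_droplets(mito, config = config$binarization))
    atg <- unclass(segment_droplets(atg, config = config$binarization))
  }
  mito <- mito != 0; atg <- atg != 0
  start <- select_window(mito, config)
  nz <- dim(mito)[3L]
  end <- start + config$n_slices - 1L
  clipped <- end > nz
  if (clipped) {
    warning(sprintf("only %d of %d requested slices available after start slice %d; window clipped",
                    nz - start + 1L, config$n_slices, start))
    end <- nz
  }
  window <- start:end
  ratios <- vapply(window, function(z) {
    m <- sum(mito[, , z])
    if (m == 0L) 0 else sum(mito[, , z] & atg[, , z]) / m
  }, numeric(1))
  structure(
    list(index = sum(ratios), per_slice_ratio = ratios,
         window_start = start, n_slices_used = length(window),
         clipped = clipped),
    class = "mitophagy_result")
}

#' @export
print.mitophagy_result <- function(x, ...) {
  cat(sprintf("<mitophagy_result> index %.3f over %d slices from slice %d%s\n",
              x$index, x$n_slices_used, x$window_start,
              if (x$clipped) " (window clipped)" else ""))
  invisible(x)
}
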