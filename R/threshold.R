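#' Build a 256-bin intensity histogram
#'
#' Bins intensities over the observed data range (after mask exclusion)
#' into `n_bins` equal-width, left-closed bins; the top bin is closed on
#' both sides. Integer-valued data whose range fits within `n_bins`
#' levels are binned at unit width (as for 8-bit images), which avoids
#' artificial empty bins between populated intensity levels. A constant
#' image yields a single-bin (degenerate) histogram, which the
#' auto-threshold functions reject.
#'
#' @param x Numeric vector, matrix or array of intensities (`NA` ignored).
#' @param n_bins Number of bins (default 256).
#' @param range Optional `c(lo, hi)` intensity range; defaults to the data
#'   range.
#' @return An object of class `intensity_histogram`: `counts` (length
#'   `n_bins`), `breaks` (length `n_bins + 1`), `mids`.
#' @export
intensity_histogram <- function(x, n_bins = 256, range = NULL) {
  v <- as.numeric(x)
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("no unmasked pixels to histogram")
  if (is.null(range)) range <- c(min(v), max(v))
  lo <- range[1L]; hi <- range[2L]
  integerish <- all(v == round(v)) && hi - lo <= n_bins - 1L && hi > lo
  if (hi <= lo) {
    counts <- c(length(v), integer(n_bins - 1L))
    breaks <- seq(lo, lo + 1, length.out = n_bins + 1L)
  } else if (integerish) {
    counts <- tabulate(v - lo + 1L, nbins = n_bins)
    breaks <- seq(lo - 0.5, lo + n_bins - 0.5, by = 1)
  } else {
    w <- (hi - lo) / n_bins
    idx <- pmin(pmax(floor((v - lo) / w), 0), n_bins - 1L) + 1L
    counts <- tabulate(idx, nbins = n_bins)
    breaks <- seq(lo, hi, length.out = n_bins + 1L)
  }
  structure(list(counts = as.integer(counts), breaks = breaks,
                 mids = (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2),
            class = "intensity_histogram")
}

hist_counts <- function(hist) {
  if (inherits(hist, "intensity_histogram")) hist$counts else as.numeric(hist)
}

#' Triangle auto-threshold
#'
#' Standard triangle method: a chord is drawn from the histogram peak to
#' the farthest nonzero tail bin on the longer-tail side, and the
#' threshold is the bin maximizing the perpendicular distance from the
#' histogram curve to that chord. Ties break to the lowest qualifying
#' bin. Foreground is intensity in bins strictly above the returned bin.
#'
#' @param hist An [intensity_histogram()] or a bare vector of bin counts.
#' @return Threshold bin index (1-based), with attribute `side`
#'   (`"right"` or `"left"`, the tail used).
#' @export
triangle_threshold <- function(hist) {
  h <- hist_counts(hist)
  nz <- which(h > 0)
  if (length(nz) < 2L) stop("degenerate histogram: fewer than 2 nonzero bins")
  peak <- which.max(h)
  lo <- nz[1L]; hi <- nz[length(nz)]
  side <- if ((hi - peak) >= (peak - lo)) "right" else "left"
  end <- if (side == "right") hi else lo
  cand <- if (side == "right") seq(peak, end) else seq(end, peak)
  # perpendicular distance from (i, h[i]) to the chord (peak,h[peak])-(end,h[end])
  dx <- end - peak; dy <- h[end] - h[peak]
  d <- abs(dy * (cand - peak) - dx * (h[cand] - h[peak])) / sqrt(dx^2 + dy^2)
  t <- cand[which.max(d)]  # which.max: first (lowest) index on ties
  structure(as.integer(t), side = side)
}

# Renyi entropy of order alpha for the two classes split at each
# candidate bin t (background = bins 1..t, foreground = t+1..n).
# Returns the entropic sum for every bin where both classes have mass.
renyi_entropic_sums <- function(p, alpha) {
  n <- length(p)
  P1 <- cumsum(p)
  out <- rep(-Inf, n)
  for (t in seq_len(n - 1L)) {
    if (P1[t] <= 0 || P1[t] >= 1) next
    pb <- p[1:t] / P1[t]
    pf <- p[(t + 1L):n] / (1 - P1[t])
    pb <- pb[pb > 0]; pf <- pf[pf > 0]
    if (abs(alpha - 1) < 1e-12) {
      out[t] <- -sum(pb * log(pb)) - sum(pf * log(pf))
    } else {
      out[t] <- (log(sum(pb^alpha)) + log(sum(pf^alpha))) / (1 - alpha)
    }
  }
  out
}

#' Renyi-entropy auto-threshold
#'
#' Entropy-based threshold of Sahoo, Wilkins and Yeager: the entropic sum
#' of the background and foreground class distributions is maximized at
#' three entropic orders (alpha = 0.5, 1, 2; alpha = 1 is the Shannon /
#' Kapur limit), and the three maximizers `t1 <= t2 <= t3` are combined as
#' \deqn{t^* = t1 (P(t1) + 0.25 w b1) + 0.25 t2 w b2 + t3 (1 - P(t3) + 0.25 w b3)}
#' with `w = P(t3) - P(t1)`, weights `(b1,b2,b3) = (1,2,1)` when
#' `|t1 - t3| <= 5` bins and `(0,1,3)` otherwise, truncated to a bin
#' index. Per-order ties break to the lowest bin.
#'
#' @param hist An [intensity_histogram()] or a bare vector of bin counts.
#' @param alpha Optional single entropic order: return that order's
#'   maximizer only (no combination).
#' @return Threshold bin index (1-based); for the combined rule, the
#'   per-order maximizers are attached as attribute `alpha_thresholds`
#'   (named by alpha).
#' @export
renyi_entropy_threshold <- function(hist, alpha = NULL) {
  h <- hist_counts(hist)
  if (sum(h > 0) < 2L) stop("degenerate histogram: fewer than 2 nonzero bins")
  p <- h / sum(h)
  if (!is.null(alpha))
    return(which.max(renyi_entropic_sums(p, alpha)))
  alphas <- c(0.5, 1, 2)
  ts <- vapply(alphas, function(a) which.max(renyi_entropic_sums(p, a)), integer(1))
  names(ts) <- alphas
  P1 <- cumsum(p)
  s <- sort(ts)
  t1 <- s[1L]; t2 <- s[2L]; t3 <- s[3L]
  if (abs(t1 - t3) <= 5) {
    b <- c(1, 2, 1)
  } else {
    b <- c(0, 1, 3)
  }
  w <- P1[t3] - P1[t1]
  t_star <- t1 * (P1[t1] + 0.25 * w * b[1L]) +
    0.25 * t2 * w * b[2L] +
    t3 * (1 - P1[t3] + 0.25 * w * b[3L])
  t_star <- max(1L, min(length(p), as.integer(floor(t_star))))
  structure(t_star, alpha_thresholds = ts)
}

#' Segmentation configuration for droplet analysis
#'
#' @param method `"triangle"`, `"renyi"` or `"fixed"`.
#' @param mode `"per_slice"` (threshold each z slice independently) or
#'   `"max_projection"` (maximum-project, then threshold once).
#' @param connectivity 4 or 8 (2D pixel connectivity; 8 matches common
#'   particle-analysis behavior).
#' @param min_area_px Drop components smaller than this (default 0: no
#'   size filter).
#' @param fixed_threshold Intensity cutoff when `method = "fixed"`
#'   (foreground is strictly above it).
#' @param n_bins Histogram bins for the auto-threshold methods.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(method = c("triangle", "renyi", "fixed"),
                                mode = c("per_slice", "max_projection"),
                                connectivity = 8, min_area_px = 0,
                                fixed_threshold = NULL, n_bins = 256) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  if (min_area_px < 0) stop("min_area_px must be >= 0")
  if (method == "fixed" && (is.null(fixed_threshold) || fixed_threshold < 0))
    stop("method 'fixed' requires a nonnegative fixed_threshold")
  structure(list(method = method, mode = mode,
                 connectivity = as.integer(connectivity),
                 min_area_px = as.integer(min_area_px),
                 fixed_threshold = fixed_threshold, n_bins = as.integer(n_bins)),
            class = "segmentation_config")
}

# Threshold one 2D image (NA = masked). Returns logical foreground.
# A degenerate (single-bin) image yields no foreground with a warning.
threshold_image <- function(img, config) {
  fg <- matrix(FALSE, nrow(img), ncol(img))
  ok <- !is.na(img)
  if (!any(ok)) return(list(foreground = fg, threshold = NA_real_))
  if (config$method == "fixed") {
    fg[ok] <- img[ok] > config$fixed_threshold
    return(list(foreground = fg, threshold = config$fixed_threshold))
  }
  hist <- intensity_histogram(img[ok], n_bins = config$n_bins)
  if (sum(hist$counts > 0) < 2L) {
    warning("degenerate (constant) image: no foreground segmented")
    return(list(foreground = fg, threshold = NA_real_))
  }
  t_bin <- if (config$method == "triangle") triangle_threshold(hist)
           else renyi_entropy_threshold(hist)
  cut <- hist$breaks[as.integer(t_bin) + 1L]  # upper edge of threshold bin
  fg[ok] <- img[ok] > cut
  list(foreground = fg, threshold = cut)
}

#' Segment lipid droplets by auto-thresholding
#'
#' Binarizes a stack either slice by slice or on a maximum z projection,
#' using the configured auto-threshold. Masked pixels are removed before
#' histogramming and excluded from the analyzed area.
#'
#' @param stack A [channel_stack()] or array.
#' @param mask Optional exclusion mask (nonzero = exclude).
#' @param config A [segmentation_config()].
#' @return Logical array (per-slice mode) or logical matrix wrapped as a
#'   one-slice array (projection mode), class `droplet_segmentation`,
#'   with attributes `thresholds` (intensity cut per slice),
#'   `analyzed_px` (unmasked pixels per slice) and `mode`.
#' @export
segment_droplets <- function(stack, mask = NULL, config = segmentation_config()) {
  arr <- as_stack_array(stack)
  if (!is.null(mask)) arr <- apply_exclusion_mask(arr, mask)
  if (all(is.na(arr))) stop("fully masked input: nothing to segment")
  if (config$mode == "max_projection") {
    proj <- apply(arr, c(1L, 2L), function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
    arr <- array(proj, dim = c(dim(proj), 1L))
  }
  nz <- dim(arr)[3L]
  fg <- array(FALSE, dim = dim(arr))
  thresholds <- numeric(nz)
  analyzed <- integer(nz)
  for (z in seq_len(nz)) {
    res <- threshold_image(arr[, , z], config)
    fg[, , z] <- res$foreground
    thresholds[z] <- res$threshold
    analyzed[z] <- sum(!is.na(arr[, , z]))
  }
  structure(fg, thresholds = thresholds, analyzed_px = analyzed,
            mode = config$mode, class = c("droplet_segmentation", "array"))
}

#' Label connected components of a 2D binary image
#'
#' @param img Logical (or 0/1) matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(img, connectivity = 8) {
  if (!is.matrix(img)) stop("img must be a matrix")
  .label_components_cpp(img != 0 & !is.na(img), as.integer(connectivity))
}

#' Droplet count, area fraction and mean size
#'
#' Runs 2D connected-component analysis on a binarized stack (per slice,
#' or on the single projection plane) and aggregates particle metrics per
#' brain. In per-slice mode, component counts are summed across slices
#' with no 3D linking, so a droplet spanning several slices contributes
#' once per slice (matching slice-wise particle analysis).
#'
#' @param binary Output of [segment_droplets()], or any logical stack.
#' @param connectivity 4 or 8.
#' @param min_area_px Components smaller than this are dropped.
#' @param analyzed_px Total analyzed (unmasked) pixels; defaults to the
#'   `analyzed_px` attribute of `binary`, else all pixels.
#' @return Object of class `droplet_morphometry`: `count`,
#'   `fractional_area`, `mean_size_px` (`NA` when `count` is 0),
#'   `total_area_px`, `analyzed_px` and a `per_slice` data frame.
#' @export
droplet_metrics <- function(binary, connectivity = 8, min_area_px = 0,
                            analyzed_px = NULL) {
  arr <- as_stack_array(binary)
  if (is.null(analyzed_px)) {
    ap <- attr(binary, "analyzed_px")
    analyzed_px <- if (is.null(ap)) length(arr) else sum(ap)
  }
  nz <- dim(arr)[3L]
  per_slice <- lapply(seq_len(nz), function(z) {
    lab <- label_components(arr[, , z] != 0, connectivity)
    sizes <- tabulate(lab, nbins = max(lab))
    sizes <- sizes[sizes >= max(1L, min_area_px)]
    data.frame(slice = z, count = length(sizes), area_px = sum(sizes))
  })
  per_slice <- do.call(rbind, per_slice)
  count <- sum(per_slice$count)
  total_area <- sum(per_slice$area_px)
  structure(
    list(count = count,
         fractional_area = if (analyzed_px > 0) total_area / analyzed_px else 0,
         mean_size_px = if (count > 0) total_area / count else NA_real_,
         total_area_px = total_area,
         analyzed_px = analyzed_px,
         per_slice = per_slice),
    class = "droplet_morphometry")
}

#' @export
print.droplet_morphometry <- function(x, ...) {
  cat(sprintf("<droplet_morphometry> %d droplets, %.4f area fraction, mean size %s px\n",
              x$count, x$fractional_area,
              if (is.na(x$mean_size_px)) "NA" else sprintf("%.1f", x$mean_size_px)))
  invisible(x)
}
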