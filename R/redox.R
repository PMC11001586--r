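#' Ratio-gating configuration for ratiometric sensors
#'
#' Holds the per-pixel ratio gate and background-exclusion factor used
#' when scoring two-channel redox stacks. Presets encode the constants
#' used for each sensor/driver combination:
#' \describe{
#'   \item{`rogfp`}{mito-roGFP2-Grx1: ratios outside 0.25x-4x excluded;
#'     pixels below 0.5x the channel mean excluded.}
#'   \item{`mitotimer_repo`}{MitoTimer, glial driver: gate 1/2.5x-2.5x,
#'     background factor 0.4.}
#'   \item{`mitotimer_nsyb`}{MitoTimer, pan-neuronal driver: gate
#'     0.25x-4x, background factor 0.25.}
#' }
#'
#' @param preset One of `"rogfp"`, `"mitotimer_repo"`, `"mitotimer_nsyb"`.
#' @param ratio_low,ratio_high Inclusive per-pixel ratio gate; override
#'   the preset when given.
#' @param bg_factor Pixels dimmer than `bg_factor` times the channel mean
#'   (computed over ratio-gate survivors) are excluded.
#' @param numerator_label,denominator_label Channel names for reporting.
#' @return An object of class `ratio_config`.
#' @export
ratio_config <- function(preset = c("rogfp", "mitotimer_repo", "mitotimer_nsyb"),
                         ratio_low = NULL, ratio_high = NULL, bg_factor = NULL,
                         numerator_label = "405", denominator_label = "488") {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    rogfp          = c(0.25, 4.0, 0.5),
    mitotimer_repo = c(1 / 2.5, 2.5, 0.4),
    mitotimer_nsyb = c(0.25, 4.0, 0.25))
  cfg <- list(
    ratio_low = if (is.null(ratio_low)) defaults[1L] else ratio_low,
    ratio_high = if (is.null(ratio_high)) defaults[2L] else ratio_high,
    bg_factor = if (is.null(bg_factor)) defaults[3L] else bg_factor,
    numerator_label = numerator_label, denominator_label = denominator_label,
    preset = preset)
  if (!(cfg$ratio_low > 0 && cfg$ratio_low < cfg$ratio_high))
    stop("require 0 < ratio_low < ratio_high")
  if (cfg$bg_factor <= 0) stop("bg_factor must be positive")
  structure(cfg, class = "ratio_config")
}

#' Per-brain ratiometric oxidation score
#'
#' Divides two channel stacks pixel by pixel and returns the mean ratio
#' over pixels surviving two exclusion passes, in order:
#' \enumerate{
#'   \item ratio gate: pixels with ratio outside
#'     `[ratio_low, ratio_high]` (including zero-denominator pixels,
#'     whose ratio is out of bounds by definition) are excluded;
#'   \item background gate: among survivors, pixels dimmer than
#'     `bg_factor` times that channel's survivor mean, in either channel,
#'     are excluded.
#' }
#' The per-brain statistic is the arithmetic mean of the surviving
#' per-pixel ratios. Pixels flagged by an exclusion mask are removed
#' before any gating and do not enter the accounting.
#'
#' @param numerator,denominator [channel_stack()]s (or arrays) of equal
#'   shape; the ratio is `numerator / denominator`.
#' @param config A [ratio_config()].
#' @param mask Optional exclusion mask (nonzero = exclude).
#' @param per_slice Also report the mean included ratio per z slice.
#' @return Object of class `ratio_result`: `mean_ratio`, pixel accounting
#'   (`n_included`, `n_excluded_ratio`, `n_excluded_bg`, `n_masked`,
#'   `n_total`), and optional `per_slice_means`.
#' @export
compute_ratio_result <- function(numerator, denominator, config = ratio_config(),
                                 mask = NULL, per_slice = FALSE) {
  num <- as_stack_array(numerator)
  den <- as_stack_array(denominator)
  if (!all(dim(num) == dim(den))) stop("channel stacks must share shape")
  stopifnot(inherits(config, "ratio_config"))
  if (!is.null(mask)) {
    num <- apply_exclusion_mask(num, mask)
    den <- apply_exclusion_mask(den, mask)
  }
  considered <- !is.na(num) & !is.na(den)
  n_total <- length(num)
  n_masked <- n_total - sum(considered)
  ratio <- num / den  # Inf/NaN where den == 0: fails the gate below
  in_gate <- considered & is.finite(ratio) &
    ratio >= config$ratio_low & ratio <= config$ratio_high
  n_excluded_ratio <- sum(considered) - sum(in_gate)
  if (!any(in_gate)) stop("no signal: all pixels excluded by the ratio gate")
  mean_num <- mean(num[in_gate])
  mean_den <- mean(den[in_gate])
  included <- in_gate & num >= config$bg_factor * mean_num &
    den >= config$bg_factor * mean_den
  n_excluded_bg <- sum(in_gate) - sum(included)
  if (!any(included)) stop("no signal: all pixels excluded by the background gate")
  res <- list(
    mean_ratio = mean(ratio[included]),
    n_included = sum(included),
    n_excluded_ratio = n_excluded_ratio,
    n_excluded_bg = n_excluded_bg,
    n_masked = n_masked,
    n_total = n_total,
    config = config)
  if (per_slice) {
    nz <- dim(num)[3L]
    res$per_slice_means <- vapply(seq_len(nz), function(z) {
      inc <- included[, , z]
      if (any(inc)) mean(ratio[, , z][inc]) else NA_real_
    }, numeric(1))
  }
  structure(res, class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, ...) {
  cat(sprintf(
    "<ratio_result> mean ratio %.4f over %d px (%d ratio-excluded, %d background-excluded)\n",
    x$mean_ratio, x$n_included, x$n_excluded_ratio, x$n_excluded_bg))
  invisible(x)
}

#' Sensor calibration from maximal/minimal oxidation references
#'
#' @param da_mean Mean control-normalized sensor value under a maximal
#'   oxidant (diamide).
#' @param dtt_mean Mean value under a reductant (dithiothreitol).
#' @param cell_type Label, e.g. `"neuron"` or `"glia"`.
#' @return An object of class `redox_calibration`. The dynamic range
#'   `da_mean / dtt_mean` is reported by `print()`.
#' @export
redox_calibration <- function(da_mean, dtt_mean, cell_type = "") {
  if (!(da_mean > dtt_mean && dtt_mean > 0))
    stop("require da_mean > dtt_mean > 0")
  structure(list(da_mean = da_mean, dtt_mean = dtt_mean,
                 cell_type = cell_type),
            class = "redox_calibration")
}

#' @export
print.redox_calibration <- function(x, ...) {
  cat(sprintf("<redox_calibration>%s DA %.3f, DTT %.3f (dynamic range %.2f)\n",
              if (nzchar(x$cell_type)) paste0(" ", x$cell_type, ":") else "",
              x$da_mean, x$dtt_mean, x$da_mean / x$dtt_mean))
  invisible(x)
}

#' Percent oxidation of a sensor reading
#'
#' Linearly rescales a control-normalized sensor value between the
#' reductant (0%) and oxidant (100%) calibration points:
#' `100 * (x - DTT) / (DA - DTT)`. Values outside 0-100% are returned
#' as-is with attribute `out_of_range = TRUE` and a warning.
#'
#' @param x Control-normalized per-brain value(s).
#' @param cal A [redox_calibration()].
#' @return Percent oxidized, same length as `x`.
#' @export
percent_oxidized <- function(x, cal) {
  stopifnot(inherits(cal, "redox_calibration"))
  if (cal$da_mean == cal$dtt_mean) stop("calibration has zero dynamic range")
  pct <- 100 * (x - cal$dtt_mean) / (cal$da_mean - cal$dtt_mean)
  oor <- pct < 0 | pct > 100
  if (any(oor)) {
    warning("percent oxidized outside [0, 100]: value beyond the calibration range")
    attr(pct, "out_of_range") <- oor
  }
  pct
}

#' Normalize per-brain values to a control-group mean
#'
#' Divides every value by the mean of the control group, so the control
#' group's normalized mean is exactly 1. Used within each experiment
#' before pooling across repeats.
#'
#' @param values Numeric per-brain statistics.
#' @param control_values Same statistic for the control group.
#' @return `values / mean(control_values)`.
#' @export
normalize_to_group_mean <- function(values, control_values) {
  if (length(control_values) == 0L) stop("control group is empty")
  m <- mean(control_values)
  if (!is.finite(m) || m <= 0) stop("control mean must be positive")
  values / m
}

#' CaLexA activity index (GFP:RFP total-signal ratio)
#'
#' Ratio of total projected GFP to total projected RFP signal. With the
#' default sum projection this equals the ratio of whole-stack sums; a
#' maximum projection is available as an option.
#'
#' @param gfp,rfp [channel_stack()]s of equal shape.
#' @param projection `"sum"` (default) or `"max"`.
#' @return A single ratio.
#' @export
calexa_index <- function(gfp, rfp, projection = c("sum", "max")) {
  projection <- match.arg(projection)
  g <- as_stack_array(gfp); r <- as_stack_array(rfp)
  if (!all(dim(g) == dim(r))) stop("channel stacks must share shape")
  proj <- function(a) apply(a, c(1L, 2L), if (projection == "sum") sum else max)
  tot_r <- sum(proj(r))
  if (tot_r <= 0) stop("total RFP signal is zero")
  sum(proj(g)) / tot_r
}

#' Mean lipid-peroxidation (MDA) staining intensity
#'
#' Sums all z slices of a stack into one projection, then averages the
#' projected pixels strictly above a background exclusion threshold. The
#' threshold is held constant across brains within an experiment.
#'
#' @param stack A [channel_stack()] or array.
#' @param bg_threshold Background exclusion threshold (projected-intensity
#'   units, >= 0).
#' @param mask Optional exclusion mask applied before projection.
#' @return Mean projected intensity above threshold.
#' @export
mda_mean_intensity <- function(stack, bg_threshold, mask = NULL) {
  if (bg_threshold < 0) stop("bg_threshold must be nonnegative")
  arr <- as_stack_array(stack)
  if (!is.null(mask)) arr <- apply_exclusion_mask(arr, mask)
  proj <- apply(arr, c(1L, 2L), sum)
  keep <- !is.na(proj) & proj > bg_threshold
  if (!any(keep)) stop("no pixels above the background threshold")
  mean(proj[keep])
}
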