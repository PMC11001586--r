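#' Construct an OCR trace
#'
#' One well's oxygen consumption rate series from an extracellular flux
#' run, one value per mix/wait/measure cycle (default 1 min / 30 s /
#' 3 min, i.e. 4.5 min per cycle), with a 6-cycle baseline before
#' injection.
#'
#' @param ocr Numeric vector of positive OCR values (pmol O2/min).
#' @param well_id Well label.
#' @param n_baseline_cycles Baseline cycles recorded before injection.
#' @param injection_cycle Cycle index of drug injection (defaults to the
#'   cycle after baseline).
#' @param cycle_minutes Minutes per cycle.
#' @param injection_failed Manual flag: drug visibly failed to inject
#'   (detected by cartridge inspection, not inferred from the trace).
#' @return Object of class `ocr_trace`.
#' @export
ocr_trace <- function(ocr, well_id = "well", n_baseline_cycles = 6,
                      injection_cycle = n_baseline_cycles + 1,
                      cycle_minutes = 4.5, injection_failed = FALSE) {
  ocr <- as.numeric(ocr)
  if (!all(is.finite(ocr)) || any(ocr <= 0)) stop("OCR values must be positive and finite")
  if (length(ocr) <= n_baseline_cycles)
    stop("trace must extend beyond the baseline period")
  structure(list(ocr = ocr, well_id = as.character(well_id),
                 n_baseline_cycles = as.integer(n_baseline_cycles),
                 injection_cycle = as.integer(injection_cycle),
                 cycle_minutes = cycle_minutes,
                 injection_failed = isTRUE(injection_failed)),
            class = "ocr_trace")
}

#' Normalize an OCR trace to its late-baseline level
#'
#' Divides every value by the mean OCR over the last `reference_cycles`
#' baseline cycles ("the end of the baseline period"), so the reference
#' window has mean 1 by construction.
#'
#' @param trace An [ocr_trace()].
#' @param reference_cycles Number of terminal baseline cycles defining
#'   the reference level (default 3).
#' @return Numeric normalized series.
#' @export
normalize_baseline <- function(trace, reference_cycles = 3) {
  stopifnot(inherits(trace, "ocr_trace"))
  nb <- trace$n_baseline_cycles
  if (reference_cycles < 1 || reference_cycles > nb)
    stop("reference_cycles must lie in [1, n_baseline_cycles]")
  ref <- mean(trace$ocr[(nb - reference_cycles + 1L):nb])
  if (!is.finite(ref) || ref <= 0) stop("nonpositive baseline reference mean")
  trace$ocr / ref
}

#' Flag unstable OCR wells
#'
#' A well is excluded when any two consecutive raw measurements differ by
#' more than `max_rel_step` of the earlier value (default 30%), in either
#' direction: sudden steps arise when tissue shifts away from the sensor
#' probe during mixing. The bound is strict -- a step of exactly 30% is
#' kept (a tiny relative tolerance absorbs floating-point representation
#' error at the boundary). Injection failure is a manual flag carried on
#' the trace, not inferred.
#'
#' @param trace An [ocr_trace()].
#' @param max_rel_step Exclusion bound on |change|/previous value.
#' @param reference_cycles Passed to [normalize_baseline()] for the
#'   normalized series in the report.
#' @return Object of class `ocr_qc_report`: `well_id`, `normalized`,
#'   `excluded`, `reason` (`"unstable_step"`, `"injection_failure"` or
#'   `"none"`), `max_rel_step` observed.
#' @export
flag_unstable <- function(trace, max_rel_step = 0.30, reference_cycles = 3) {
  stopifnot(inherits(trace, "ocr_trace"))
  x <- trace$ocr
  if (length(x) < 2L) stop("trace must have at least 2 cycles")
  rel <- abs(diff(x)) / x[-length(x)]
  worst <- max(rel)
  tol <- max_rel_step * 1e-9
  if (trace$injection_failed) {
    excluded <- TRUE; reason <- "injection_failure"
  } else if (worst > max_rel_step + tol) {
    excluded <- TRUE; reason <- "unstable_step"
  } else {
    excluded <- FALSE; reason <- "none"
  }
  structure(list(well_id = trace$well_id,
                 normalized = normalize_baseline(trace, reference_cycles),
                 excluded = excluded, reason = reason,
                 max_rel_step = worst),
            class = "ocr_qc_report")
}

#' Per-cycle group summary over QC-passing wells
#'
#' @param reports List of [flag_unstable()] reports.
#' @return List with `summary` (data frame: cycle, mean, sem, n) over
#'   non-excluded wells and `excluded` (data frame of well_id, reason).
#' @export
summarize_group <- function(reports) {
  kept <- Filter(function(r) !r$excluded, reports)
  if (length(kept) == 0L) stop("all wells excluded")
  mat <- vapply(kept, function(r) r$normalized, numeric(length(kept[[1L]]$normalized)))
  mat <- matrix(mat, ncol = length(kept))
  excl <- Filter(function(r) r$excluded, reports)
  list(
    summary = data.frame(
      cycle = seq_len(nrow(mat)),
      mean = rowMeans(mat),
      sem = apply(mat, 1L, sem),
      n = length(kept)),
    excluded = data.frame(
      well_id = vapply(excl, function(r) r$well_id, character(1)),
      reason = vapply(excl, function(r) r$reason, character(1))))
}

#' Read OCR traces from a tidy CSV
#'
#' Expects columns `well_id`, `cycle`, `ocr` and optionally
#' `injection_failed` (logical/0-1 per well).
#'
#' @param path CSV path.
#' @param n_baseline_cycles,cycle_minutes Passed to [ocr_trace()].
#' @return List of [ocr_trace()] objects, one per well.
#' @export
read_ocr_table <- function(path, n_baseline_cycles = 6, cycle_minutes = 4.5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well_id", "cycle", "ocr")
  if (!all(need %in% names(df)))
    stop("OCR table must contain columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$well_id), function(w) {
    w <- w[order(w$cycle), ]
    ocr_trace(w$ocr, well_id = w$well_id[1L],
              n_baseline_cycles = n_baseline_cycles,
              cycle_minutes = cycle_minutes,
              injection_failed = "injection_failed" %in% names(w) &&
                any(w$injection_failed %in% c(TRUE, 1)))
  })
}
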