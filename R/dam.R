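#' Construct an activity trace
#'
#' An activity trace holds one fly's beam-break counts in 1-minute bins,
#' aligned to a Zeitgeber time (ZT) grid. ZT0 is lights-on of a 12:12
#' light:dark cycle; `start_zt` gives the ZT minute of the first bin.
#'
#' @param counts Integer vector of nonnegative per-minute activity counts.
#' @param fly_id Character label for the fly (monitor/channel).
#' @param start_zt ZT offset of the first bin, in minutes (0 to 1439).
#' @param lights_on_min,lights_off_min Minutes within the 1440-min day at
#'   which lights switch on and off. Defaults encode a 12:12 cycle with
#'   lights-on at ZT0.
#' @param alive_through Index of the last analyzable minute (defaults to
#'   the full trace). Minutes beyond it are ignored by all metrics.
#' @return An object of class `activity_trace`.
#' @export
activity_trace <- function(counts, fly_id = "fly", start_zt = 0,
                           lights_on_min = 0, lights_off_min = 720,
                           alive_through = length(counts)) {
  counts <- as.integer(counts)
  if (length(counts) < 1L) stop("activity trace must contain at least one minute")
  if (anyNA(counts) || any(counts < 0L)) stop("activity counts must be nonnegative integers")
  if (start_zt < 0 || start_zt >= 1440) stop("start_zt must lie in [0, 1440)")
  if (alive_through < 1L || alive_through > length(counts))
    stop("alive_through must index into the trace")
  structure(
    list(fly_id = as.character(fly_id), counts = counts,
         start_zt = as.integer(start_zt),
         lights_on_min = as.integer(lights_on_min),
         lights_off_min = as.integer(lights_off_min),
         alive_through = as.integer(alive_through)),
    class = "activity_trace")
}

#' @export
print.activity_trace <- function(x, ...) {
  cat(sprintf("<activity_trace> %s: %d min from ZT%.1f, %d total counts\n",
              x$fly_id, length(x$counts), x$start_zt / 60, sum(x$counts)))
  invisible(x)
}

#' Read a TriKinetics DAM monitor file
#'
#' Parses the de-facto standard DAM dialect: tab-separated rows with a
#' record index, date (`"%d %b %y"`), time (`HH:MM:SS`), a status code
#' (only status-OK rows, code 1, are accepted), six device fields and then
#' 32 channel counts. Rows must be chronological at exactly 1-minute
#' spacing.
#'
#' @param path Path to a monitor file.
#' @param channel_map Optional character vector of 32 fly ids; defaults to
#'   `ch01`..`ch32` prefixed by the file name.
#' @param lights_on Clock time of lights-on as `"HH:MM"`; used to place
#'   the recording on the ZT grid.
#' @return A list of [activity_trace()] objects, one per channel.
#' @export
read_dam_monitor <- function(path, channel_map = NULL, lights_on = "08:00") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("monitor file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 42L)
  if (length(bad) > 0L)
    stop(sprintf("malformed monitor row at line %d: expected 42 tab-separated fields, found %d",
                 bad[1L], nf[bad[1L]]))
  m <- do.call(rbind, fields)
  status <- suppressWarnings(as.integer(m[, 4L]))
  keep <- !is.na(status) & status == 1L
  if (!any(keep)) stop("monitor file contains no status-OK rows: ", path)
  m <- m[keep, , drop = FALSE]
  tstamp <- dam_parse_time(m[, 2L], m[, 3L])
  if (anyNA(tstamp)) {
    bad <- which(keep)[which(is.na(tstamp))[1L]]
    stop(sprintf("unparseable timestamp at line %d", bad))
  }
  dt <- diff(tstamp)
  if (length(dt) > 0L && any(dt != 60)) {
    bad <- which(keep)[which(dt != 60)[1L] + 1L]
    stop(sprintf("timestamps must advance by exactly 1 min; violation at line %d", bad))
  }
  counts <- matrix(suppressWarnings(as.integer(m[, 11:42, drop = FALSE])), ncol = 32L)
  if (anyNA(counts) || any(counts < 0L))
    stop("channel counts must be nonnegative integers")
  if (is.null(channel_map)) {
    channel_map <- sprintf("%s_ch%02d", sub("\\.[^.]*$", "", basename(path)), 1:32)
  } else if (length(channel_map) != 32L) {
    stop("channel_map must supply 32 labels")
  }
  lo <- clock_to_min(lights_on)
  first_min <- (as.integer(tstamp[1L] / 60) %% 1440L)
  start_zt <- (first_min - lo) %% 1440L
  lapply(seq_len(32L), function(ch)
    activity_trace(counts[, ch], fly_id = channel_map[ch], start_zt = start_zt))
}

dam_parse_time <- function(date, time) {
  old <- Sys.getlocale("LC_TIME")
  on.exit(suppressWarnings(Sys.setlocale("LC_TIME", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_TIME", "C"))
  as.numeric(as.POSIXct(strptime(paste(date, time), "%d %b %y %H:%M:%S", tz = "UTC")))
}

clock_to_min <- function(hhmm) {
  parts <- as.integer(strsplit(hhmm, ":", fixed = TRUE)[[1L]])
  if (length(parts) < 2L || anyNA(parts[1:2])) stop("clock time must be HH:MM")
  parts[1L] * 60L + parts[2L]
}

#' Detect sleep bouts
#'
#' Sleep is defined as a maximal run of zero-count minutes lasting at
#' least `min_bout` minutes (5 by the standard fly-sleep convention).
#'
#' @param trace An [activity_trace()].
#' @param min_bout Minimum inactivity run length, in minutes, that counts
#'   as sleep.
#' @return A data frame with columns `start_min` (1-based index into the
#'   trace) and `duration_min`, sorted and non-overlapping.
#' @export
detect_bouts <- function(trace, min_bout = 5) {
  stopifnot(inherits(trace, "activity_trace"))
  if (min_bout < 1) stop("min_bout must be at least 1 minute")
  counts <- trace$counts[seq_len(trace$alive_through)]
  if (length(counts) == 0L) stop("empty trace")
  r <- rle(counts == 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_bout
  data.frame(start_min = starts[keep], duration_min = r$lengths[keep])
}

# Per-minute sleep flag over the analyzable trace (TRUE = asleep).
sleep_flags <- function(trace, min_bout = 5) {
  bouts <- detect_bouts(trace, min_bout)
  flags <- logical(trace$alive_through)
  for (i in seq_len(nrow(bouts)))
    flags[bouts$start_min[i]:(bouts$start_min[i] + bouts$duration_min[i] - 1L)] <- TRUE
  flags
}

# Index of the first minute falling on a ZT0 boundary.
first_day_start <- function(trace) {
  ((1440L - trace$start_zt) %% 1440L) + 1L
}

#' Per-day sleep architecture metrics
#'
#' Computes, for each full 24-h day starting at a ZT0 boundary: total
#' sleep, day/night sleep split by the light schedule, bout count, mean
#' bout duration and waking activity (counts per awake minute). Bouts
#' spanning a ZT0 boundary contribute their minutes to each day they
#' cover, but are counted (and their full duration averaged) in the day
#' in which they start, so `n_bouts * mean_bout_min` recovers total
#' unclipped bout minutes.
#'
#' @inheritParams detect_bouts
#' @return A data frame with one row per day: `day_index`,
#'   `total_sleep_min`, `day_sleep_min`, `night_sleep_min`, `n_bouts`,
#'   `mean_bout_min`, `waking_activity` (NA when no awake minutes).
#' @export
daily_metrics <- function(trace, min_bout = 5) {
  stopifnot(inherits(trace, "activity_trace"))
  d0 <- first_day_start(trace)
  n_days <- (trace$alive_through - d0 + 1L) %/% 1440L
  if (n_days < 1L)
    stop("trace must span at least one full day from a ZT0 boundary")
  flags <- sleep_flags(trace, min_bout)
  bouts <- detect_bouts(trace, min_bout)
  counts <- trace$counts
  zt <- (trace$start_zt + seq_along(counts) - 1L) %% 1440L
  is_day <- zt >= trace$lights_on_min & zt < trace$lights_off_min
  out <- lapply(seq_len(n_days), function(d) {
    idx <- (d0 + (d - 1L) * 1440L):(d0 + d * 1440L - 1L)
    in_day <- bouts$start_min >= idx[1L] & bouts$start_min <= idx[1440L]
    slept <- flags[idx]
    awake <- sum(!slept)
    data.frame(
      day_index = d,
      total_sleep_min = sum(slept),
      day_sleep_min = sum(slept & is_day[idx]),
      night_sleep_min = sum(slept & !is_day[idx]),
      n_bouts = sum(in_day),
      mean_bout_min = if (any(in_day)) mean(bouts$duration_min[in_day]) else NA_real_,
      waking_activity = if (awake > 0L) sum(counts[idx][!slept]) / awake else NA_real_)
  })
  do.call(rbind, out)
}

#' Average per-day metrics across days
#'
#' Summarises a [daily_metrics()] table across days, excluding the first
#' day by default to allow for acclimation to the monitor.
#'
#' @param metrics Data frame from [daily_metrics()].
#' @param exclude_first_day Drop day 1 before averaging (default TRUE;
#'   requires at least 2 days when set).
#' @return One-row data frame of day-averaged metrics.
#' @export
average_daily_metrics <- function(metrics, exclude_first_day = TRUE) {
  if (exclude_first_day) {
    if (nrow(metrics) < 2L)
      stop("need at least 2 days to exclude the acclimation day")
    metrics <- metrics[metrics$day_index > 1L, , drop = FALSE]
  }
  num <- vapply(metrics[-1L], function(col) mean(col, na.rm = TRUE), numeric(1))
  cbind(data.frame(n_days = nrow(metrics)), as.data.frame(as.list(num)))
}

#' Binned sleep time course across flies
#'
#' Sleep minutes per `bin_min`-minute ZT bin for each fly, with the group
#' mean and SEM per bin.
#'
#' @param traces List of [activity_trace()] objects on a common ZT grid
#'   (equal `start_zt` and length).
#' @param bin_min Bin width in minutes; must divide 1440.
#' @param min_bout Sleep definition passed to [detect_bouts()].
#' @return A data frame with `bin_start_zt` (minutes), per-bin `mean_sleep_min`,
#'   `sem_sleep_min` and `n_flies`; the per-fly matrix is attached as
#'   attribute `per_fly` (bins x flies).
#' @export
sleep_timecourse <- function(traces, bin_min = 30, min_bout = 5) {
  if (length(traces) == 0L) stop("no traces supplied")
  if (1440 %% bin_min != 0) stop("bin_min must divide 1440")
  szt <- vapply(traces, function(t) t$start_zt, integer(1))
  len <- vapply(traces, function(t) t$alive_through, integer(1))
  if (length(unique(szt)) != 1L || length(unique(len)) != 1L)
    stop("traces must share a common ZT grid (equal start_zt and length)")
  n_min <- len[1L]
  bin_of <- ((szt[1L] + seq_len(n_min) - 1L) %/% bin_min)
  per_fly <- vapply(traces, function(t) {
    tapply(as.integer(sleep_flags(t, min_bout)), bin_of, sum)
  }, numeric(length(unique(bin_of))))
  per_fly <- matrix(per_fly, nrow = length(unique(bin_of)))
  bins <- sort(unique(bin_of))
  out <- data.frame(
    bin_start_zt = (bins * bin_min) %% 1440L,
    mean_sleep_min = rowMeans(per_fly),
    sem_sleep_min = apply(per_fly, 1L, sem),
    n_flies = length(traces))
  attr(out, "per_fly") <- per_fly
  out
}

sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' Exclude flies that died during the experiment
#'
#' A fly is treated as dead when its counts are zero from some minute
#' through the end of the experiment and that terminal silent span is at
#' least `death_window` minutes (24 h by default). Dead flies are removed
#' and logged with their last-activity minute.
#'
#' @param traces List of [activity_trace()] objects.
#' @param death_window Minimum terminal zero-count span, in minutes, that
#'   marks death.
#' @return A list with elements `kept`, `excluded` (both lists of traces)
#'   and `log` (data frame of `fly_id`, `last_activity_min`, `excluded`).
#' @export
exclude_dead <- function(traces, death_window = 1440) {
  last_act <- vapply(traces, function(t) {
    nz <- which(t$counts[seq_len(t$alive_through)] > 0L)
    if (length(nz) == 0L) 0L else nz[length(nz)]
  }, integer(1))
  n <- vapply(traces, function(t) t$alive_through, integer(1))
  dead <- (n - last_act) >= death_window
  log <- data.frame(
    fly_id = vapply(traces, function(t) t$fly_id, character(1)),
    last_activity_min = last_act, excluded = dead)
  list(kept = traces[!dead], excluded = traces[dead], log = log)
}

#' Control-subtracted sleep loss with SEM propagation
#'
#' Expresses each experimental fly's metric relative to the control-group
#' mean (`exp_i - mean(ctrl)`). The SEM of the difference is propagated in
#' quadrature, `sqrt(SEM_exp^2 + SEM_ctrl^2)`, treating the groups as
#' independent. Raw groups are retained: statistical comparisons are meant
#' to run on raw, not subtracted, values.
#'
#' @param exp_values Numeric per-fly metric for the experimental group.
#' @param ctrl_values Numeric per-fly metric for the control group.
#' @return An object of class `sleep_loss_summary`: `per_fly_loss`,
#'   `group_mean_loss`, `propagated_sem`, plus the raw inputs.
#' @export
subtract_control <- function(exp_values, ctrl_values) {
  if (length(exp_values) == 0L || length(ctrl_values) == 0L)
    stop("both groups must be non-empty")
  loss <- exp_values - mean(ctrl_values)
  structure(
    list(per_fly_loss = loss,
         group_mean_loss = mean(loss),
         propagated_sem = sqrt(sem(exp_values)^2 + sem(ctrl_values)^2),
         raw_exp = exp_values, raw_ctrl = ctrl_values),
    class = "sleep_loss_summary")
}

#' @export
print.sleep_loss_summary <- function(x, ...) {
  cat(sprintf("<sleep_loss_summary> mean loss %.2f +/- %.2f (SEM, propagated), n = %d vs %d\n",
              x$group_mean_loss, x$propagated_sem,
              length(x$raw_exp), length(x$raw_ctrl)))
  invisible(x)
}
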