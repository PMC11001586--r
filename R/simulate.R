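# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so generators are pure in (params, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Generate a synthetic lipid-droplet scene
#'
#' Draws `n_droplets` non-overlapping filled disks of random radius over
#' a flat background and adds photon-limited (Poisson) or additive
#' Gaussian noise. Ground truth (centers, radii, exact foreground mask
#' and pixel areas) is returned alongside the image, so segmentation and
#' morphometry can be scored against known answers. No optical blur is
#' simulated: droplet edges are sharp.
#'
#' @param n_droplets Number of disks.
#' @param image_size `c(rows, cols)`; single-slice scenes (stack scenes
#'   are built by stacking calls).
#' @param radius_range `c(min, max)` disk radius in pixels; a disk of
#'   radius r covers the pixels within Euclidean distance r of its
#'   center.
#' @param fg_mean,bg_mean Foreground and background mean intensities.
#' @param noise `"poisson"` (default; variance = mean, the photon-limited
#'   regime) or `"gaussian"`.
#' @param gaussian_sd Noise SD when `noise = "gaussian"`.
#' @param min_separation Minimum center-to-center distance between disks;
#'   defaults to `2 * max radius + 3` so disks never touch.
#' @param max_tries Rejection-sampling budget for disk placement.
#' @param seed RNG seed; identical `(params, seed)` give identical scenes.
#' @return List: `image` (matrix), `truth` (list: `centers` data frame,
#'   `radii`, `mask`, `count`, `total_area_px`, `snr`).
#' @export
gen_droplet_scene <- function(n_droplets = 50, image_size = c(256, 256),
                              radius_range = c(4, 4), fg_mean = 150,
                              bg_mean = 10, noise = c("poisson", "gaussian"),
                              gaussian_sd = 10,
                              min_separation = 2 * max(radius_range) + 3,
                              max_tries = 20000, seed = NULL) {
  noise <- match.arg(noise)
  nr <- image_size[1L]; nc <- image_size[2L]
  with_seed(seed, {
    rmax <- max(radius_range)
    centers <- matrix(numeric(0), ncol = 2L)
    radii <- numeric(0)
    tries <- 0L
    while (nrow(centers) < n_droplets) {
      if (tries >= max_tries)
        stop("could not place droplets at the requested separation (infeasible packing)")
      tries <- tries + 1L
      r <- if (radius_range[1L] == radius_range[2L]) radius_range[1L]
           else stats::runif(1, radius_range[1L], radius_range[2L])
      cy <- stats::runif(1, r + 1, nr - r)
      cx <- stats::runif(1, r + 1, nc - r)
      if (nrow(centers) > 0L &&
          any(sqrt((centers[, 1L] - cy)^2 + (centers[, 2L] - cx)^2) < min_separation))
        next
      centers <- rbind(centers, c(cy, cx))
      radii <- c(radii, r)
    }
    mask <- matrix(FALSE, nr, nc)
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    for (i in seq_len(nrow(centers)))
      mask <- mask | ((rows - centers[i, 1L])^2 + (cols - centers[i, 2L])^2 <= radii[i]^2)
    clean <- matrix(bg_mean, nr, nc)
    clean[mask] <- fg_mean
    img <- if (noise == "poisson") {
      matrix(stats::rpois(nr * nc, as.vector(clean)), nr, nc)
    } else {
      pmax(clean + matrix(stats::rnorm(nr * nc, 0, gaussian_sd), nr, nc), 0)
    }
    snr <- if (noise == "poisson") (fg_mean - bg_mean) / sqrt(fg_mean)
           else (fg_mean - bg_mean) / gaussian_sd
    list(image = img,
         truth = list(
           centers = data.frame(row = centers[, 1L], col = centers[, 2L]),
           radii = radii, mask = mask, count = n_droplets,
           total_area_px = sum(mask), snr = snr))
  })
}

#' Generate a synthetic two-channel redox scene
#'
#' Signal pixels carry a known numerator:denominator ratio `true_ratio`
#' (denominator around `base_intensity`, numerator around
#' `true_ratio * base_intensity`); background pixels are dim in both
#' channels, below the background gate by construction. With
#' `noise_sd = 0` the per-pixel ratio of every signal pixel equals
#' `true_ratio` exactly.
#'
#' @param true_ratio Ground-truth ratio of signal pixels (must lie
#'   inside the ratio gate to be recoverable).
#' @param signal_fraction Fraction of pixels carrying signal.
#' @param base_intensity Denominator-channel signal level.
#' @param background_intensity Background level in both channels.
#' @param noise_sd Additive Gaussian noise SD on signal pixels (SNR =
#'   `base_intensity / noise_sd`).
#' @param dim `c(rows, cols, slices)`.
#' @param seed RNG seed.
#' @return List: `numerator`, `denominator` ([channel_stack()]s),
#'   `truth` (list: `true_ratio`, `signal_mask`, `snr`).
#' @export
gen_redox_scene <- function(true_ratio = 2, signal_fraction = 0.3,
                            base_intensity = 100, background_intensity = 5,
                            noise_sd = 0, dim = c(64, 64, 4), seed = NULL) {
  if (signal_fraction <= 0 || signal_fraction > 1)
    stop("signal_fraction must lie in (0, 1]")
  with_seed(seed, {
    n <- prod(dim)
    n_sig <- round(n * signal_fraction)
    sig <- array(FALSE, dim)
    sig[sample.int(n, n_sig)] <- TRUE
    den <- array(background_intensity, dim)
    num <- array(background_intensity, dim)
    if (noise_sd > 0) {
      den[sig] <- pmax(base_intensity + stats::rnorm(n_sig, 0, noise_sd), 1)
      num[sig] <- pmax(true_ratio * base_intensity +
                         stats::rnorm(n_sig, 0, noise_sd), 1)
    } else {
      den[sig] <- base_intensity
      num[sig] <- true_ratio * base_intensity
    }
    list(numerator = channel_stack(num, "405"),
         denominator = channel_stack(den, "488"),
         truth = list(true_ratio = true_ratio, signal_mask = sig,
                      snr = if (noise_sd > 0) base_intensity / noise_sd else Inf))
  })
}

#' Generate paired mask stacks with exact per-slice overlap fractions
#'
#' Builds binary mitochondria/autophagosome stacks whose per-slice
#' colocalized-to-mitochondrial area ratio equals the requested
#' `overlap_fractions` exactly: each slice places `mito_px`
#' mitochondrial pixels at random, of which exactly
#' `f_z * mito_px` (an integer by requirement) are also autophagosome
#' pixels.
#'
#' @param overlap_fractions Vector of per-slice fractions in [0, 1];
#'   `f_z * mito_px` must be integral.
#' @param mito_px Mitochondrial pixels per slice.
#' @param dim_2d `c(rows, cols)` slice size.
#' @param atg_extra_px Extra autophagosome-only pixels per slice.
#' @param seed RNG seed.
#' @return List: `mito`, `atg` (logical arrays), `truth` (list:
#'   `overlap_fractions`, `expected_index = sum(overlap_fractions)`).
#' @export
gen_coloc_scene <- function(overlap_fractions, mito_px = 100,
                            dim_2d = c(32, 32), atg_extra_px = 20,
                            seed = NULL) {
  f <- overlap_fractions
  if (any(f < 0 | f > 1)) stop("overlap fractions must lie in [0, 1]")
  ov <- f * mito_px
  if (any(abs(ov - round(ov)) > 1e-9))
    stop(sprintf("overlap fractions must be multiples of 1/mito_px; try mito_px divisible by the fraction denominators (mito_px = %d)", mito_px))
  ov <- as.integer(round(ov))
  npx <- prod(dim_2d)
  if (mito_px + atg_extra_px > npx) stop("slice too small for the requested pixel budget")
  nz <- length(f)
  with_seed(seed, {
    mito <- array(FALSE, c(dim_2d, nz))
    atg <- array(FALSE, c(dim_2d, nz))
    for (z in seq_len(nz)) {
      px <- sample.int(npx, mito_px + atg_extra_px)
      m <- px[seq_len(mito_px)]
      sl_m <- matrix(FALSE, dim_2d[1L], dim_2d[2L]); sl_m[m] <- TRUE
      sl_a <- matrix(FALSE, dim_2d[1L], dim_2d[2L])
      if (ov[z] > 0L) sl_a[m[seq_len(ov[z])]] <- TRUE
      if (atg_extra_px > 0L) sl_a[px[(mito_px + 1L):(mito_px + atg_extra_px)]] <- TRUE
      mito[, , z] <- sl_m
      atg[, , z] <- sl_a
    }
    list(mito = mito, atg = atg,
         truth = list(overlap_fractions = f, expected_index = sum(f)))
  })
}

#' Generate DAM activity traces with known sleep architecture
#'
#' Simulates each fly as an alternating wake/sleep renewal process:
#' bout lengths are geometric (memoryless, integer minutes) with
#' phase-specific means for sleep (day vs night at bout onset), wake
#' minutes carry Poisson activity counts clipped to at least 1 (so wake
#' is never misread as sleep), and sleep minutes are silent. Minutes
#' inside a mechanical sleep-deprivation window are forced active
#' (counts >= 1), modelling sub-minute shaking at the 1-min DAM
#' resolution. Ground-truth bout lists and totals are computed from the
#' emitted counts themselves by run-length analysis, so they are exact
#' by construction.
#'
#' @param n_flies Number of flies (channels).
#' @param n_days Days of recording, starting at ZT0.
#' @param sleep_bout_mean_day,sleep_bout_mean_night Mean sleep-bout
#'   length (min) for bouts starting in the light/dark phase.
#' @param wake_bout_mean Mean wake-bout length (min).
#' @param activity_rate Poisson mean of counts per waking minute.
#' @param deprivation_window `c(start, end)` in ZT minutes (end may
#'   exceed 1440 to span into the next day), or `NULL`.
#' @param deprivation_days Day indices (1-based) on which the window
#'   applies.
#' @param min_bout Sleep definition used for the emitted ground truth.
#' @param seed RNG seed.
#' @return List: `traces` (list of [activity_trace()]), `truth` (per-fly
#'   list: `bouts` data frame, `total_sleep_min`).
#' @export
gen_dam_traces <- function(n_flies = 32, n_days = 2,
                           sleep_bout_mean_day = 20,
                           sleep_bout_mean_night = 60,
                           wake_bout_mean = 15, activity_rate = 2,
                           deprivation_window = NULL,
                           deprivation_days = seq_len(n_days),
                           min_bout = 5, seed = NULL) {
  stopifnot(sleep_bout_mean_day >= 1, sleep_bout_mean_night >= 1,
            wake_bout_mean >= 1, activity_rate > 0)
  n_min <- n_days * 1440L
  depr <- logical(n_min)
  if (!is.null(deprivation_window)) {
    for (d in deprivation_days) {
      idx <- ((d - 1L) * 1440L + deprivation_window[1L] + 1L):
             ((d - 1L) * 1440L + deprivation_window[2L])
      depr[idx[idx >= 1L & idx <= n_min]] <- TRUE
    }
  }
  rgeom1 <- function(mean_len) 1L + stats::rgeom(1L, 1 / mean_len)
  with_seed(seed, {
    traces <- vector("list", n_flies)
    truth <- vector("list", n_flies)
    for (fl in seq_len(n_flies)) {
      counts <- integer(n_min)
      pos <- 1L
      asleep <- FALSE
      while (pos <= n_min) {
        if (asleep) {
          zt <- (pos - 1L) %% 1440L
          mean_len <- if (zt < 720L) sleep_bout_mean_day else sleep_bout_mean_night
          len <- rgeom1(mean_len)
          # sleep minutes stay zero
        } else {
          len <- rgeom1(wake_bout_mean)
          idx <- pos:min(pos + len - 1L, n_min)
          counts[idx] <- pmax(stats::rpois(length(idx), activity_rate), 1L)
        }
        pos <- pos + len
        asleep <- !asleep
      }
      counts[depr] <- pmax(counts[depr], 1L)
      # ground truth from the emitted counts themselves
      r <- rle(counts == 0L)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values & r$lengths >= min_bout
      bouts <- data.frame(start_min = starts[keep], duration_min = r$lengths[keep])
      traces[[fl]] <- activity_trace(counts, fly_id = sprintf("sim_ch%02d", fl))
      truth[[fl]] <- list(bouts = bouts, total_sleep_min = sum(bouts$duration_min))
    }
    list(traces = traces, truth = truth)
  })
}

#' Write activity traces as a TriKinetics monitor file
#'
#' Emits the standard DAM dialect read by [read_dam_monitor()]: one row
#' per minute with record index, date, time, status code 1, six zero
#' device fields and 32 channel counts (missing channels padded with
#' zeros; at most 32 traces per file).
#'
#' @param traces List of [activity_trace()]s on a common grid.
#' @param path Output path.
#' @param start_clock Clock time of the first row, `"HH:MM"`; pair with
#'   the `lights_on` argument of [read_dam_monitor()] to set the ZT grid.
#' @param start_date Date of the first row (`Date` or `"%Y-%m-%d"`).
#' @return `path`, invisibly.
#' @export
write_dam_monitor <- function(traces, path, start_clock = "08:00",
                              start_date = as.Date("2024-01-01")) {
  if (length(traces) > 32L) stop("a monitor file holds at most 32 channels")
  n_min <- unique(vapply(traces, function(t) length(t$counts), integer(1)))
  if (length(n_min) != 1L) stop("all traces must share length")
  counts <- vapply(traces, function(t) t$counts, integer(n_min))
  counts <- matrix(counts, nrow = n_min)
  if (ncol(counts) < 32L)
    counts <- cbind(counts, matrix(0L, n_min, 32L - ncol(counts)))
  t0 <- as.POSIXct(paste(as.Date(start_date), paste0(start_clock, ":00")), tz = "UTC")
  tt <- t0 + 60 * (seq_len(n_min) - 1L)
  old <- Sys.getlocale("LC_TIME")
  on.exit(suppressWarnings(Sys.setlocale("LC_TIME", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_TIME", "C"))
  rows <- paste(
    seq_len(n_min),
    format(tt, "%d %b %y"),
    format(tt, "%H:%M:%S"),
    1L, 1L, 0L, 0L, 0L, 0L, 0L,
    apply(counts, 1L, paste, collapse = "\t"),
    sep = "\t")
  writeLines(rows, path)
  invisible(path)
}

#' Generate synthetic OCR traces with injected step artifacts
#'
#' Builds per-well OCR series with a stable baseline, a smooth
#' post-injection decline (rotenone-like), small multiplicative drift
#' and noise, and -- in a labeled fraction of wells -- one abrupt
#' relative step exceeding the instability bound. Ground-truth
#' clean/artifact labels accompany the data.
#'
#' @param n_wells Number of wells.
#' @param n_cycles Total measurement cycles.
#' @param n_baseline_cycles Baseline cycles before injection.
#' @param baseline_level Baseline OCR (pmol O2/min).
#' @param post_injection_decline Per-cycle multiplicative decline after
#'   injection (e.g. 0.96 for a gradual rotenone response).
#' @param drift_per_cycle Multiplicative drift per cycle on the baseline.
#' @param noise_cv Coefficient of variation of multiplicative noise.
#' @param step_fraction Fraction of wells given an artifact step.
#' @param step_size Relative size of the injected step (e.g. 0.4 = 40%).
#' @param seed RNG seed.
#' @return List: `traces` (list of [ocr_trace()]), `truth` (data frame:
#'   `well_id`, `has_step`, `step_cycle`).
#' @export
gen_ocr_traces <- function(n_wells = 12, n_cycles = 38, n_baseline_cycles = 6,
                           baseline_level = 8, post_injection_decline = 0.96,
                           drift_per_cycle = 1.0, noise_cv = 0.01,
                           step_fraction = 0.25, step_size = 0.4, seed = NULL) {
  if (step_fraction < 0 || step_fraction > 1) stop("step_fraction must lie in [0, 1]")
  with_seed(seed, {
    n_step <- round(n_wells * step_fraction)
    has_step <- c(rep(TRUE, n_step), rep(FALSE, n_wells - n_step))
    traces <- vector("list", n_wells)
    step_cycle <- rep(NA_integer_, n_wells)
    for (w in seq_len(n_wells)) {
      level <- baseline_level * drift_per_cycle^(seq_len(n_cycles) - 1L)
      post <- seq_len(n_cycles) > n_baseline_cycles
      level[post] <- level[post] *
        post_injection_decline^(seq_len(sum(post)))
      x <- level * (1 + stats::rnorm(n_cycles, 0, noise_cv))
      if (has_step[w]) {
        sc <- sample((n_baseline_cycles + 2L):(n_cycles - 1L), 1L)
        # anchor the step to the previous realized value so the emitted
        # consecutive change is exactly step_size
        x[sc:n_cycles] <- x[sc:n_cycles] * (1 + step_size) * x[sc - 1L] / x[sc]
        step_cycle[w] <- sc
      }
      traces[[w]] <- ocr_trace(pmax(x, 1e-6), well_id = sprintf("W%02d", w),
                               n_baseline_cycles = n_baseline_cycles)
    }
    list(traces = traces,
         truth = data.frame(well_id = sprintf("W%02d", seq_len(n_wells)),
                            has_step = has_step, step_cycle = step_cycle))
  })
}

#' Write OCR traces as a tidy CSV
#'
#' @param traces List of [ocr_trace()]s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ocr_table <- function(traces, path) {
  df <- do.call(rbind, lapply(traces, function(t)
    data.frame(well_id = t$well_id, cycle = seq_along(t$ocr), ocr = t$ocr,
               injection_failed = t$injection_failed)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
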