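# Allowed keys per config block; validate_config rejects anything else.
config_schema <- function() {
  list(
    top = c("seed", "out_dir", "stages"),
    stages = c("simulate_dam", "simulate_ocr", "sleep", "droplets",
               "redox", "mitophagy", "ocr", "stats"),
    simulate_dam = list(
      n_flies = 8, n_days = 2, sleep_bout_mean_day = 20,
      sleep_bout_mean_night = 60, wake_bout_mean = 15, activity_rate = 2,
      deprivation_start_zt = NULL, deprivation_end_zt = NULL),
    simulate_ocr = list(
      n_wells = 12, n_cycles = 38, n_baseline_cycles = 6,
      baseline_level = 8, step_fraction = 0.25, step_size = 0.4),
    sleep = list(monitor = NULL, lights_on = "08:00", min_bout = 5,
                 bin_min = 30, exclude_dead = TRUE, death_window = 1440),
    droplets = list(stack = NULL, mask = NULL, method = "triangle",
                    mode = "per_slice", connectivity = 8, min_area_px = 0),
    redox = list(numerator = NULL, denominator = NULL, mask = NULL,
                 preset = "rogfp", da = NULL, dtt = NULL),
    mitophagy = list(mito = NULL, atg = NULL, n_slices = 30,
                     start_mode = "max_mito_area", binarized = TRUE),
    ocr = list(table = NULL, baseline_cycles = 6, reference_cycles = 3,
               max_rel_step = 0.30),
    stats = list(table = NULL, reference = NULL, alpha = 0.05,
                 alpha_gate = 0.05))
}

#' Validate a pipeline configuration file
#'
#' Reads a YAML run configuration, rejects unknown keys at any level,
#' checks parameter ranges and the existence of referenced input files,
#' and fills defaults. Every default applied is recorded.
#'
#' @param path Path to a YAML config.
#' @return Object of class `run_config`: `seed`, `out_dir`, `stages`
#'   (fully resolved parameter blocks), `defaults_applied` (character
#'   log), `config_path`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  schema <- config_schema()
  errors <- character(0)
  unknown <- setdiff(names(raw), schema$top)
  if (length(unknown) > 0L)
    errors <- c(errors, paste0("unknown top-level key: ", unknown))
  stages <- raw$stages
  if (is.null(stages) || length(stages) == 0L)
    errors <- c(errors, "config must define at least one stage under 'stages'")
  unknown_stage <- setdiff(names(stages), schema$stages)
  if (length(unknown_stage) > 0L)
    errors <- c(errors, paste0("unknown stage: ", unknown_stage))
  defaults_applied <- character(0)
  resolved <- list()
  file_keys <- c("monitor", "stack", "mask", "numerator", "denominator",
                 "mito", "atg", "table")
  simulated_inputs <- c(
    if ("simulate_dam" %in% names(stages)) "sleep.monitor",
    if ("simulate_ocr" %in% names(stages)) "ocr.table")
  for (st in intersect(names(stages), schema$stages)) {
    block <- stages[[st]]
    if (is.null(block)) block <- list()
    allowed <- schema[[st]]
    unknown <- setdiff(names(block), names(allowed))
    if (length(unknown) > 0L)
      errors <- c(errors, paste0("unknown key in stage '", st, "': ", unknown))
    for (key in names(allowed)) {
      if (is.null(block[[key]])) {
        if (!is.null(allowed[[key]])) {
          block[[key]] <- allowed[[key]]
          defaults_applied <- c(defaults_applied,
                                sprintf("%s.%s = %s (default)", st, key,
                                        format(allowed[[key]])))
        }
      }
    }
    for (key in intersect(names(block), file_keys)) {
      ref <- block[[key]]
      if (is.null(ref)) {
        if (!paste0(st, ".", key) %in% simulated_inputs &&
            !(st == "droplets" && key == "mask") &&
            !(st == "redox" && key == "mask"))
          errors <- c(errors, sprintf("stage '%s' requires input '%s'", st, key))
      } else if (!file.exists(ref)) {
        errors <- c(errors, sprintf("stage '%s': input file not found: %s", st, ref))
      }
    }
    resolved[[st]] <- block
  }
  if ("redox" %in% names(resolved)) {
    blk <- resolved$redox
    if (!is.null(blk$da) && !is.null(blk$dtt) && !(blk$da > blk$dtt))
      errors <- c(errors, "redox calibration requires da > dtt")
  }
  seed <- raw$seed
  if (is.null(seed)) {
    seed <- 1L
    defaults_applied <- c(defaults_applied, "seed = 1 (default)")
  }
  if (!is.numeric(seed) || seed != as.integer(seed))
    errors <- c(errors, "seed must be an integer")
  out_dir <- if (is.null(raw$out_dir)) "mitosleep_run" else raw$out_dir
  if (length(errors) > 0L)
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 stages = resolved, defaults_applied = defaults_applied,
                 config_path = normalizePath(path)),
            class = "run_config")
}

write_csv_out <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the configured pipeline stages
#'
#' Executes the stages of a validated configuration in a fixed order
#' (simulators first, then analyses), writing tidy CSV outputs and a
#' JSON manifest to the run directory. All randomness derives from the
#' configured seed, so rerunning the same config on the same inputs
#' reproduces every tabular output bit-identically. Inputs are never
#' mutated.
#'
#' @param config A [validate_config()] result, or a path to a YAML
#'   config.
#' @return Invisibly, a list of per-stage outputs; side effect: files
#'   under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- config$stages
  results <- list()
  outputs <- character(0)

  if (!is.null(st$simulate_dam)) {
    p <- st$simulate_dam
    depr <- if (!is.null(p$deprivation_start_zt))
      c(p$deprivation_start_zt, p$deprivation_end_zt) else NULL
    sim <- gen_dam_traces(n_flies = p$n_flies, n_days = p$n_days,
                          sleep_bout_mean_day = p$sleep_bout_mean_day,
                          sleep_bout_mean_night = p$sleep_bout_mean_night,
                          wake_bout_mean = p$wake_bout_mean,
                          activity_rate = p$activity_rate,
                          deprivation_window = depr, seed = config$seed)
    mon <- file.path(config$out_dir, "simulated_monitor.txt")
    write_dam_monitor(sim$traces, mon)
    channel_map <- c(vapply(sim$traces, function(t) t$fly_id, character(1)),
                     sprintf("empty_ch%02d", seq_len(32 - length(sim$traces))))
    truth <- do.call(rbind, lapply(seq_along(sim$truth), function(i)
      data.frame(fly_id = sim$traces[[i]]$fly_id,
                 total_sleep_min = sim$truth[[i]]$total_sleep_min)))
    outputs <- c(outputs, mon, write_csv_out(truth, config$out_dir, "dam_truth.csv"))
    results$simulate_dam <- list(monitor = mon, truth = sim$truth,
                                 channel_map = channel_map)
  }

  if (!is.null(st$simulate_ocr)) {
    p <- st$simulate_ocr
    sim <- gen_ocr_traces(n_wells = p$n_wells, n_cycles = p$n_cycles,
                          n_baseline_cycles = p$n_baseline_cycles,
                          baseline_level = p$baseline_level,
                          step_fraction = p$step_fraction,
                          step_size = p$step_size, seed = config$seed)
    tab <- file.path(config$out_dir, "simulated_ocr.csv")
    write_ocr_table(sim$traces, tab)
    outputs <- c(outputs, tab,
                 write_csv_out(sim$truth, config$out_dir, "ocr_truth.csv"))
    results$simulate_ocr <- list(table = tab, truth = sim$truth)
  }

  if (!is.null(st$sleep)) {
    p <- st$sleep
    monitor <- if (!is.null(p$monitor)) p$monitor else results$simulate_dam$monitor
    if (is.null(monitor)) stop("sleep stage has no monitor input")
    cmap <- if (is.null(p$monitor)) results$simulate_dam$channel_map else NULL
    traces <- read_dam_monitor(monitor, channel_map = cmap,
                               lights_on = p$lights_on)
    if (isTRUE(p$exclude_dead)) {
      part <- exclude_dead(traces, death_window = p$death_window)
      writeLines(sprintf("%s\tlast_activity_min=%d\texcluded=%s",
                         part$log$fly_id, part$log$last_activity_min,
                         part$log$excluded),
                 file.path(config$out_dir, "exclusion_log.txt"))
      traces <- part$kept
    }
    traces <- Filter(function(t) sum(t$counts) > 0, traces)
    if (length(traces) == 0L) stop("sleep stage: no live flies with activity")
    per_day <- do.call(rbind, lapply(traces, function(t)
      cbind(fly_id = t$fly_id, daily_metrics(t, min_bout = p$min_bout))))
    bouts <- do.call(rbind, lapply(traces, function(t)
      cbind(fly_id = t$fly_id, detect_bouts(t, min_bout = p$min_bout))))
    tc <- sleep_timecourse(traces, bin_min = p$bin_min, min_bout = p$min_bout)
    outputs <- c(outputs,
                 write_csv_out(per_day, config$out_dir, "sleep_daily_metrics.csv"),
                 write_csv_out(bouts, config$out_dir, "sleep_bouts.csv"),
                 write_csv_out(tc, config$out_dir, "sleep_timecourse.csv"))
    results$sleep <- list(per_day = per_day, bouts = bouts, timecourse = tc)
  }

  if (!is.null(st$droplets)) {
    p <- st$droplets
    stack <- read_stack(p$stack)
    mask <- if (!is.null(p$mask)) read_stack(p$mask) else NULL
    cfg <- segmentation_config(method = p$method, mode = p$mode,
                               connectivity = p$connectivity,
                               min_area_px = p$min_area_px)
    seg <- segment_droplets(stack, mask = mask, config = cfg)
    met <- droplet_metrics(seg, connectivity = cfg$connectivity,
                           min_area_px = cfg$min_area_px)
    df <- data.frame(stack = p$stack, method = p$method, mode = p$mode,
                     count = met$count, fractional_area = met$fractional_area,
                     mean_size_px = met$mean_size_px,
                     total_area_px = met$total_area_px,
                     analyzed_px = met$analyzed_px)
    outputs <- c(outputs, write_csv_out(df, config$out_dir, "droplet_metrics.csv"))
    results$droplets <- met
  }

  if (!is.null(st$redox)) {
    p <- st$redox
    num <- read_stack(p$numerator, "num")
    den <- read_stack(p$denominator, "den")
    mask <- if (!is.null(p$mask)) read_stack(p$mask) else NULL
    res <- compute_ratio_result(num, den, config = ratio_config(p$preset),
                                mask = mask)
    df <- data.frame(numerator = p$numerator, denominator = p$denominator,
                     preset = p$preset, mean_ratio = res$mean_ratio,
                     n_included = res$n_included,
                     n_excluded_ratio = res$n_excluded_ratio,
                     n_excluded_bg = res$n_excluded_bg)
    if (!is.null(p$da) && !is.null(p$dtt))
      df$percent_oxidized <- suppressWarnings(
        percent_oxidized(res$mean_ratio, redox_calibration(p$da, p$dtt)))
    outputs <- c(outputs, write_csv_out(df, config$out_dir, "redox_result.csv"))
    results$redox <- res
  }

  if (!is.null(st$mitophagy)) {
    p <- st$mitophagy
    cfg <- coloc_config(n_slices = p$n_slices, start_mode = p$start_mode)
    res <- coloc_index(read_stack(p$mito, "mito"), read_stack(p$atg, "atg"),
                       config = cfg, binarized = isTRUE(p$binarized))
    df <- data.frame(mito = p$mito, atg = p$atg, index = res$index,
                     window_start = res$window_start,
                     n_slices_used = res$n_slices_used, clipped = res$clipped)
    outputs <- c(outputs, write_csv_out(df, config$out_dir, "mitophagy_index.csv"))
    results$mitophagy <- res
  }

  if (!is.null(st$ocr)) {
    p <- st$ocr
    tab <- if (!is.null(p$table)) p$table else results$simulate_ocr$table
    if (is.null(tab)) stop("ocr stage has no table input")
    traces <- read_ocr_table(tab, n_baseline_cycles = p$baseline_cycles)
    reports <- lapply(traces, flag_unstable, max_rel_step = p$max_rel_step,
                      reference_cycles = p$reference_cycles)
    qc <- do.call(rbind, lapply(reports, function(r)
      data.frame(well_id = r$well_id, excluded = r$excluded,
                 reason = r$reason, max_rel_step = r$max_rel_step)))
    grp <- summarize_group(reports)
    outputs <- c(outputs,
                 write_csv_out(qc, config$out_dir, "ocr_qc.csv"),
                 write_csv_out(grp$summary, config$out_dir, "ocr_group_summary.csv"))
    results$ocr <- list(qc = qc, summary = grp$summary)
  }

  if (!is.null(st$stats)) {
    p <- st$stats
    df <- utils::read.csv(p$table, stringsAsFactors = FALSE)
    groups <- split(df$value, df$group)
    ref <- if (!is.null(p$reference)) p$reference else names(groups)[1L]
    res <- compare_groups(group_set(groups, reference_label = ref),
                          alpha = p$alpha, alpha_gate = p$alpha_gate)
    out <- cbind(data.frame(branch = res$branch, tests = res$tests_used,
                            omnibus_p = res$omnibus_p), res$comparisons)
    outputs <- c(outputs, write_csv_out(out, config$out_dir, "stats_comparisons.csv"))
    results$stats <- res
  }

  input_files <- as.character(unlist(lapply(st, function(b)
    Filter(function(v) is.character(v) && file.exists(v), b))))
  manifest <- list(
    package = "mitosleep",
    version = as.character(utils::packageVersion("mitosleep")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(config$config_path)),
    stages = names(st),
    defaults_applied = config$defaults_applied,
    input_md5 = as.list(tools::md5sum(unique(unname(input_files)))),
    outputs = basename(outputs))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
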