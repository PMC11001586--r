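test_that("baseline normalization uses the late-baseline mean", {
  t1 <- ocr_trace(rep(8, 10))
  expect_equal(normalize_baseline(t1), rep(1, 10))
  # last-3 baseline mean 2.0; post-injection value 1.0 -> 0.5
  t2 <- ocr_trace(c(3, 3, 3, 2, 2, 2, 1, 1))
  expect_equal(normalize_baseline(t2)[7], 0.5)
  # scale invariance
  set.seed(2)
  x <- rlnorm(20, 2, 0.1)
  t3 <- ocr_trace(x)
  expect_equal(normalize_baseline(t3), normalize_baseline(ocr_trace(17.3 * x)))
  # elementwise division oracle
  expect_equal(normalize_baseline(t3), x / mean(x[4:6]))
  expect_error(normalize_baseline(t3, reference_cycles = 7), "reference_cycles")
})

test_that("instability flagging is strict at the 30% boundary, both directions", {
  base <- c(rep(1, 6))
  expect_true(flag_unstable(ocr_trace(c(base, 1.35)))$excluded)   # 35% rise
  expect_false(flag_unstable(ocr_trace(c(base, 1.25)))$excluded)  # 25% rise
  expect_true(flag_unstable(ocr_trace(c(base, 0.65)))$excluded)   # 35% fall
  expect_true(flag_unstable(ocr_trace(c(base, 1.31)))$excluded)   # just above
  expect_false(flag_unstable(ocr_trace(c(base, 1.29)))$excluded)  # just below
  expect_false(flag_unstable(ocr_trace(c(base, 1.30)))$excluded)  # exactly 30%: kept
  expect_false(flag_unstable(ocr_trace(c(base, 0.70)))$excluded)  # exactly -30%: kept
  r <- flag_unstable(ocr_trace(c(base, 1.35)))
  expect_equal(r$reason, "unstable_step")
  expect_equal(r$max_rel_step, 0.35)
  # flag computed on raw values: prior normalization cannot change it
  x <- c(40, 40, 40, 40, 40, 40, 20, 18)
  expect_equal(flag_unstable(ocr_trace(x))$excluded,
               flag_unstable(ocr_trace(x / mean(x[4:6])))$excluded)
})

test_that("injection failure is a manual flag, not inferred", {
  r <- flag_unstable(ocr_trace(rep(5, 10), injection_failed = TRUE))
  expect_true(r$excluded)
  expect_equal(r$reason, "injection_failure")
})

test_that("group summaries run over kept wells only", {
  a <- flag_unstable(ocr_trace(rep(4, 8), well_id = "A"))
  b <- flag_unstable(ocr_trace(rep(6, 8), well_id = "B"))
  bad <- flag_unstable(ocr_trace(c(rep(4, 6), 8, 8), well_id = "C"))
  s <- summarize_group(list(a, b, bad))
  expect_equal(s$summary$n, rep(2, 8))
  expect_equal(s$summary$sem, rep(0, 8))  # both kept wells normalize to 1
  expect_equal(s$excluded$well_id, "C")
  expect_error(summarize_group(list(bad)), "all wells excluded")
  # recomputation oracle on a seeded cohort
  sim <- gen_ocr_traces(n_wells = 8, step_fraction = 0.25, seed = 6)
  reports <- lapply(sim$traces, flag_unstable)
  s <- summarize_group(reports)
  kept <- !vapply(reports, function(r) r$excluded, logical(1))
  mat <- sapply(reports[kept], function(r) r$normalized)
  expect_equal(s$summary$mean, rowMeans(mat))
  expect_equal(s$summary$sem, apply(mat, 1, function(v) sd(v) / sqrt(length(v))))
})

test_that("OCR tables round-trip through CSV", {
  sim <- gen_ocr_traces(n_wells = 5, seed = 13)
  f <- withr::local_tempfile(fileext = ".csv")
  write_ocr_table(sim$traces, f)
  back <- read_ocr_table(f)
  expect_length(back, 5)
  expect_equal(back[["W03"]]$ocr, sim$traces[[3]]$ocr)
})

test_that("generated step artifacts are flagged exactly by construction", {
  # noise-free boundary cohort: 31% steps flagged, 29% kept
  hi <- gen_ocr_traces(n_wells = 6, step_fraction = 0.5, step_size = 0.31,
                       noise_cv = 0, post_injection_decline = 1, seed = 1)
  lo <- gen_ocr_traces(n_wells = 6, step_fraction = 0.5, step_size = 0.29,
                       noise_cv = 0, post_injection_decline = 1, seed = 1)
  flag_hi <- vapply(hi$traces, function(t) flag_unstable(t)$excluded, logical(1))
  flag_lo <- vapply(lo$traces, function(t) flag_unstable(t)$excluded, logical(1))
  expect_equal(flag_hi, hi$truth$has_step)
  expect_false(any(flag_lo))
  # clean cohort at vanishing noise: nothing flagged
  clean <- gen_ocr_traces(n_wells = 6, step_fraction = 0, noise_cv = 1e-5, seed = 2)
  expect_false(any(vapply(clean$traces, function(t) flag_unstable(t)$excluded,
                          logical(1))))
})
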