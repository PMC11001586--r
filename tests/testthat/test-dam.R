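test_that("monitor files round-trip and malformed files are rejected", {
  sim <- gen_dam_traces(n_flies = 4, n_days = 1, seed = 11)
  path <- withr::local_tempfile(fileext = ".txt")
  write_dam_monitor(sim$traces, path)
  traces <- read_dam_monitor(path)
  expect_length(traces, 32)
  for (i in 1:4)
    expect_identical(traces[[i]]$counts, sim$traces[[i]]$counts)
  expect_true(all(vapply(traces[5:32], function(t) sum(t$counts), numeric(1)) == 0))

  # hand-built 3-row fixture, channel 1 counts 0,5,0
  rows <- sprintf("%d\t01 Jan 24\t08:0%d:00\t1\t1\t0\t0\t0\t0\t0\t%d%s",
                  1:3, 0:2, c(0L, 5L, 0L), strrep("\t0", 31))
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(rows, f)
  tr <- read_dam_monitor(f)
  expect_identical(tr[[1]]$counts, c(0L, 5L, 0L))
  expect_equal(tr[[1]]$start_zt, 0)

  # 2-min timestamp jump
  bad <- rows
  bad[3] <- sub("08:02:00", "08:04:00", bad[3])
  writeLines(bad, f)
  expect_error(read_dam_monitor(f), "1 min")

  # wrong column count names the line
  writeLines(c(rows[1], "2\t01 Jan 24\t08:01:00\t1\t0"), f)
  expect_error(read_dam_monitor(f), "line 2")

  writeLines(character(0), f)
  expect_error(read_dam_monitor(f), "empty")
})

test_that("sleep bouts are maximal zero runs of at least min_bout minutes", {
  expect_equal(detect_bouts(activity_trace(rep(0L, 1440))),
               data.frame(start_min = 1L, duration_min = 1440L))
  # 4-min inactivity is not sleep; 5 min is
  expect_equal(nrow(detect_bouts(activity_trace(c(1, 0, 0, 0, 0, 1)))), 0)
  expect_equal(detect_bouts(activity_trace(c(1, 0, 0, 0, 0, 0, 1))),
               data.frame(start_min = 2L, duration_min = 5L))
  # any positive activity everywhere destroys all sleep
  expect_equal(nrow(detect_bouts(activity_trace(rep(3L, 1440)))), 0)
})

test_that("bout detection matches the run-scan oracle on random traces", {
  set.seed(42)
  for (i in 1:200) {
    counts <- rbinom(300, 1, runif(1, 0.1, 0.9)) * rpois(300, 2)
    tr <- activity_trace(counts)
    expect_identical(detect_bouts(tr),
                     oracle_bouts(counts),
                     info = paste("trace", i))
  }
})

test_that("daily metrics split days at ZT0 and account bouts exactly", {
  # one all-zero day
  m <- daily_metrics(activity_trace(rep(0L, 1440)))
  expect_equal(m$total_sleep_min, 1440)
  expect_equal(m$n_bouts, 1)
  expect_equal(m$mean_bout_min, 1440)
  expect_true(is.na(m$waking_activity))
  expect_equal(m$day_sleep_min + m$night_sleep_min, m$total_sleep_min)

  # active light phase, silent dark phase
  m <- daily_metrics(activity_trace(c(rep(2L, 720), rep(0L, 720))))
  expect_equal(m$total_sleep_min, 720)
  expect_equal(m$day_sleep_min, 0)
  expect_equal(m$night_sleep_min, 720)
  expect_equal(m$n_bouts, 1)
  expect_equal(m$waking_activity, 2.0)

  expect_error(daily_metrics(activity_trace(rep(0L, 100))), "full day")

  # per-day totals equal oracle recomputation on day slices
  set.seed(7)
  for (i in 1:20) {
    counts <- rbinom(3 * 1440, 1, 0.5) * rpois(3 * 1440, 2)
    tr <- activity_trace(counts)
    m <- daily_metrics(tr)
    flags <- oracle_sleep_flags(counts)
    for (d in 1:3) {
      idx <- ((d - 1) * 1440 + 1):(d * 1440)
      expect_equal(m$total_sleep_min[d], sum(flags[idx]))
    }
    # bout accounting identity: n_bouts * mean_bout = unclipped bout minutes
    b <- oracle_bouts(counts)
    day_of <- (b$start_min - 1) %/% 1440 + 1
    for (d in 1:3) {
      expect_equal(m$n_bouts[d], sum(day_of == d))
      if (m$n_bouts[d] > 0)
        expect_equal(m$n_bouts[d] * m$mean_bout_min[d],
                     sum(b$duration_min[day_of == d]))
    }
  }
})

test_that("multi-day summaries exclude the acclimation day", {
  counts <- c(rep(0L, 1440), rep(c(1L, rep(0L, 9)), 144))  # day1 full sleep
  m <- daily_metrics(activity_trace(counts))
  expect_equal(nrow(m), 2)
  avg <- average_daily_metrics(m)
  expect_equal(avg$n_days, 1)
  expect_equal(avg$total_sleep_min, m$total_sleep_min[2])
  expect_error(average_daily_metrics(m[1, ]), "at least 2 days")
})

test_that("sleep time course bins sum to daily totals", {
  flies <- lapply(1:5, function(i) {
    set.seed(i)
    activity_trace(rbinom(1440, 1, 0.4) * rpois(1440, 3))
  })
  tc <- sleep_timecourse(flies, bin_min = 30)
  expect_equal(nrow(tc), 48)
  per_fly <- attr(tc, "per_fly")
  for (i in 1:5) {
    expect_equal(sum(per_fly[, i]), daily_metrics(flies[[i]])$total_sleep_min)
    expect_equal(per_fly[, i],
                 as.vector(tapply(oracle_sleep_flags(flies[[i]]$counts),
                                  rep(1:48, each = 30), sum)))
  }
  # all-zero traces sleep through every bin
  zz <- lapply(1:3, function(i) activity_trace(rep(0L, 1440)))
  expect_true(all(sleep_timecourse(zz)$mean_sleep_min == 30))
  # constant activity yields no sleep anywhere
  aa <- lapply(1:3, function(i) activity_trace(rep(1L, 1440)))
  expect_true(all(sleep_timecourse(aa)$mean_sleep_min == 0))
  expect_error(sleep_timecourse(list(activity_trace(rep(0L, 1440)),
                                     activity_trace(rep(0L, 720)))),
               "common ZT grid")
})

test_that("dead flies are excluded by terminal silence", {
  alive <- activity_trace(c(rep(1L, 2000), rep(0L, 800), 1L, rep(0L, 79)))
  dead <- activity_trace(c(rep(1L, 1440), rep(0L, 1440)))
  never <- activity_trace(rep(0L, 2880))
  part <- exclude_dead(list(alive, dead, never))
  expect_length(part$kept, 1)
  expect_length(part$excluded, 2)
  expect_equal(part$log$last_activity_min, c(2801L, 1440L, 0L))
  # partition matches a last-nonzero-index scan
  set.seed(9)
  traces <- lapply(1:30, function(i) {
    n_active <- sample(0:2880, 1)
    activity_trace(c(rbinom(n_active, 1, 0.5), rep(0L, 2880 - n_active)) + 0L)
  })
  part <- exclude_dead(traces)
  manual <- vapply(traces, function(t) {
    nz <- which(t$counts > 0)
    last <- if (length(nz)) max(nz) else 0L
    (2880L - last) >= 1440L
  }, logical(1))
  expect_equal(part$log$excluded, manual)
})

test_that("control subtraction centers losses and propagates SEM in quadrature", {
  s <- subtract_control(c(10, 20), c(14, 15, 16))
  expect_equal(s$per_fly_loss, c(-5, 5))
  expect_equal(s$group_mean_loss, 0)
  # identical groups: zero mean loss
  expect_equal(subtract_control(c(3, 4, 5), c(3, 4, 5))$group_mean_loss, 0)
  # mean loss = mean(exp) - mean(ctrl)
  set.seed(1)
  e <- rnorm(12, 600, 40); c0 <- rnorm(15, 640, 35)
  s <- subtract_control(e, c0)
  expect_equal(s$group_mean_loss, mean(e) - mean(c0))
  sem <- function(x) sd(x) / sqrt(length(x))
  expect_equal(s$propagated_sem, sqrt(sem(e)^2 + sem(c0)^2))
  expect_error(subtract_control(numeric(0), c0), "non-empty")
})
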