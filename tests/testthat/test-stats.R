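test_that("the normality gate branches on Shapiro-Wilk and Levene outcomes", {
  set.seed(1)
  gaussian <- group_set(list(a = rnorm(20), b = rnorm(20)))
  g <- normality_gate(gaussian)
  expect_equal(g$branch, "parametric")
  expect_true(all(g$shapiro_p > 0.05))
  skewed <- group_set(list(a = rnorm(20), b = rexp(20, 0.2)^2))
  expect_equal(normality_gate(skewed)$branch, "nonparametric")
  # unequal variances force the nonparametric branch even when normal
  unequal <- group_set(list(a = rnorm(40, 0, 1), b = rnorm(40, 0, 12)))
  gu <- normality_gate(unequal)
  expect_lt(gu$levene_p, 0.05)
  expect_equal(gu$branch, "nonparametric")
  # degenerate group
  expect_warning(gd <- normality_gate(group_set(list(a = c(1, 1, 1), b = c(1, 2, 3)))),
                 "zero-variance")
  expect_equal(gd$branch, "nonparametric")
  expect_error(normality_gate(group_set(list(a = 1:2, b = 1:5))), "at least 3")
})

test_that("two-group comparisons pick the gated test", {
  set.seed(7)
  x <- rnorm(15); y <- rnorm(15)
  res <- compare_groups(group_set(list(a = x, b = y)))
  expect_equal(res$tests_used, "t-test (unpaired, equal variance)")
  expect_equal(res$comparisons$p_value, t.test(x, y, var.equal = TRUE)$p.value)
  xs <- exp(rnorm(15, 0, 2))
  res <- compare_groups(group_set(list(a = xs, b = y)))
  expect_equal(res$tests_used, "Mann-Whitney")
  expect_equal(res$comparisons$p_value,
               suppressWarnings(wilcox.test(xs, y))$p.value)
  # identical groups are never significant
  z <- rnorm(10)
  expect_false(compare_groups(group_set(list(a = z, b = z)))$comparisons$significant)
  # fully separated supports reach the exact-enumeration minimum for n = 10
  # (heavily skewed values so the gate selects the rank test)
  lo <- c(1, 1.1, 1.2, 1.3, 1.4, 1.5, 2, 8, 30, 100)
  hi <- lo + 1000
  res <- compare_groups(group_set(list(a = lo, b = hi)))
  expect_equal(res$tests_used, "Mann-Whitney")
  expect_equal(res$comparisons$p_value, 2 / choose(20, 10))
})

test_that("multi-group branches compare each group to the reference", {
  set.seed(15)
  groups <- list(ctrl = rnorm(12), g1 = rnorm(12, 2), g2 = rnorm(12))
  res <- compare_groups(group_set(groups, reference_label = "ctrl"))
  expect_equal(nrow(res$comparisons), 2)
  expect_true(grepl("vs ctrl", res$comparisons$comparison[1]))
  # Holm-Sidak adjustment is monotone and conservative vs raw p
  expect_true(all(diff(sort(res$comparisons$p_value)) >= 0 |
                    length(res$comparisons$p_value) == 2))
  skewed <- lapply(groups, function(g) exp(g))
  res_np <- compare_groups(group_set(skewed, reference_label = "ctrl"))
  expect_equal(res_np$branch, "nonparametric")
  expect_match(res_np$tests_used, "Dunn")
  expect_equal(res_np$omnibus_p,
               kruskal.test(unlist(skewed),
                            factor(rep(names(skewed), lengths(skewed))))$p.value)
})

test_that("Holm-Sidak matches its closed form on fixed p-values", {
  p <- c(0.01, 0.04, 0.03)
  # ordered: 0.01, 0.03, 0.04 -> 1-(1-p)^(3,2,1), cummax
  expected_sorted <- cummax(c(1 - (1 - 0.01)^3, 1 - (1 - 0.03)^2, 0.04))
  expect_equal(sort(p_adjust_holm_sidak(p)), expected_sorted)
  expect_equal(p_adjust_holm_sidak(0.2), 0.2)
})

test_that("the dual-control rule reports the most conservative p-value", {
  r <- conservative_p(0.01, 0.20)
  expect_equal(r$reported_p, 0.20)
  expect_false(r$significant)
  r <- conservative_p(0.03, 0.04)
  expect_equal(r$reported_p, 0.04)
  expect_true(r$significant)
  # boundary is strict
  expect_false(conservative_p(0.05, 0.01)$significant)
  # commutative and idempotent
  expect_equal(conservative_p(0.3, 0.07)$reported_p,
               conservative_p(0.07, 0.3)$reported_p)
  expect_equal(conservative_p(0.07, 0.07)$reported_p, 0.07)
  expect_error(conservative_p(0.01, NA), "required")
  expect_error(conservative_p(0.01, 1.2), "0, 1")
})

test_that("per-experiment normalization pools with control mean 1", {
  df <- data.frame(
    value = c(2, 2, 4, 10, 10, 30),
    group = c("ctrl", "ctrl", "exp", "ctrl", "ctrl", "exp"),
    experiment = rep(c("A", "B"), each = 3))
  out <- normalize_and_pool(df, "ctrl")
  expect_equal(out$normalized, c(1, 1, 2, 1, 1, 3))
  for (e in c("A", "B"))
    expect_equal(mean(out$normalized[out$experiment == e & out$group == "ctrl"]), 1)
  # within-experiment ratios unchanged
  sub <- out[out$experiment == "B", ]
  expect_equal(sub$normalized[3] / sub$normalized[1], sub$value[3] / sub$value[1])
  df_bad <- df[df$group != "ctrl" | df$experiment != "B", ]
  expect_error(normalize_and_pool(df_bad, "ctrl"), "experiment 'B'")
})

test_that("delta-delta-Ct reproduces hand-computed expression values", {
  tab <- data.frame(
    sample = paste0("s", 1:4),
    condition = c("control", "control", "induced", "induced"),
    ct_target = c(22, 22, 24, 25),
    ct_reference = c(18, 18, 18, 18))
  out <- qpcr_ddct(tab)
  # control dCt = 4; induced dCt = 6, 7 -> ddCt = 2, 3 -> 0.25, 0.125
  expect_equal(out$rel_expression, c(1, 1, 0.25, 0.125))
  expect_equal(mean(out$rel_expression[out$condition == "control"]), 1)
  # ddCt of exactly 1 halves expression
  tab$ct_target[3] <- 23
  expect_equal(qpcr_ddct(tab)$rel_expression[3], 0.5)
  # invariant to shifting one sample's target and reference Ct together
  tab2 <- tab
  tab2$ct_target[4] <- tab2$ct_target[4] + 3.7
  tab2$ct_reference[4] <- tab2$ct_reference[4] + 3.7
  expect_equal(qpcr_ddct(tab2)$rel_expression, qpcr_ddct(tab)$rel_expression)
  expect_error(qpcr_ddct(tab[, -4]), "columns")
  tab$ct_reference[1] <- NA
  expect_error(qpcr_ddct(tab), "finite")
})

test_that("the gated procedure keeps its nominal size under a Gaussian null", {
  res <- gated_type1_error(n_sim = 600, n_per_group = 20, dist = "gaussian",
                           seed = 99)
  expect_gt(res$rejection_rate, 0.02)
  expect_lt(res$rejection_rate, 0.09)
  expect_true("parametric" %in% names(res$branch_counts))
})
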