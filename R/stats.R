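#' Construct a labeled group set
#'
#' @param groups Named list of numeric vectors, one per group.
#' @param reference_label Name of the reference/control group (e.g. the
#'   ZT0/ZT2 or UAS control); required for multi-group designs.
#' @param design `"two_group"` or `"multi_group_vs_reference"`; inferred
#'   from the number of groups when omitted.
#' @return Object of class `group_set`.
#' @export
group_set <- function(groups, reference_label = names(groups)[1L],
                      design = NULL) {
  if (!is.list(groups) || length(groups) < 2L || is.null(names(groups)))
    stop("groups must be a named list of at least 2 numeric vectors")
  if (any(!nzchar(names(groups)))) stop("all groups must be named")
  if (!reference_label %in% names(groups))
    stop("reference_label must name one of the groups")
  if (is.null(design))
    design <- if (length(groups) == 2L) "two_group" else "multi_group_vs_reference"
  design <- match.arg(design, c("two_group", "multi_group_vs_reference"))
  structure(list(groups = lapply(groups, as.numeric),
                 reference_label = reference_label, design = design),
            class = "group_set")
}

#' Normality-gated branch selection
#'
#' The parametric branch is taken only when every group passes the
#' Shapiro-Wilk normality test AND a median-centered Levene test detects
#' no difference in variances, both at `alpha_gate`; otherwise all
#' comparisons run on the nonparametric branch. Zero-variance
#' (degenerate) groups cannot be assessed by Shapiro-Wilk and route to
#' the nonparametric branch with a warning.
#'
#' @param gs A [group_set()]; every group needs at least 3 values.
#' @param alpha_gate Gate significance level (default 0.05).
#' @return List: `branch` (`"parametric"`/`"nonparametric"`),
#'   `shapiro_p` (named per group), `levene_p`, `degenerate`.
#' @export
normality_gate <- function(gs, alpha_gate = 0.05) {
  stopifnot(inherits(gs, "group_set"))
  sizes <- lengths(gs$groups)
  if (any(sizes < 3L))
    stop("every group needs at least 3 values for the normality gate")
  degenerate <- vapply(gs$groups, function(g) stats::var(g) == 0, logical(1))
  if (any(degenerate)) {
    warning("zero-variance group(s): routing to the nonparametric branch")
    return(list(branch = "nonparametric",
                shapiro_p = rep(NA_real_, length(gs$groups)),
                levene_p = NA_real_, degenerate = degenerate))
  }
  shapiro_p <- vapply(gs$groups, function(g) stats::shapiro.test(g)$p.value,
                      numeric(1))
  values <- unlist(gs$groups, use.names = FALSE)
  labels <- factor(rep(names(gs$groups), sizes))
  levene_p <- car::leveneTest(values ~ labels, center = stats::median)[1L, "Pr(>F)"]
  branch <- if (all(shapiro_p > alpha_gate) && levene_p > alpha_gate)
    "parametric" else "nonparametric"
  list(branch = branch, shapiro_p = shapiro_p, levene_p = levene_p,
       degenerate = degenerate)
}

#' Holm-Sidak step-down adjustment
#'
#' Step-down Sidak correction: with p-values ordered ascending,
#' `p_adj_(i) = 1 - (1 - p_(i))^(m - i + 1)`, enforced monotone.
#'
#' @param p Vector of raw p-values.
#' @return Adjusted p-values in the original order.
#' @export
p_adjust_holm_sidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  adj[order(o)]
}

# Dunn's rank-based post hoc z-tests of each group against the
# reference, using the pooled mean ranks from the Kruskal-Wallis layout
# with the standard tie correction. p-values are Bonferroni-adjusted
# over the comparisons versus the reference unless correct = FALSE.
dunn_vs_reference <- function(groups, reference_label, correct = TRUE) {
  values <- unlist(groups, use.names = FALSE)
  labels <- rep(names(groups), lengths(groups))
  n <- length(values)
  rk <- rank(values)
  mean_rank <- tapply(rk, labels, mean)
  sizes <- tapply(rk, labels, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  others <- setdiff(names(groups), reference_label)
  z <- vapply(others, function(g) {
    se <- sqrt((n * (n + 1) / 12 - tie_term) *
                 (1 / sizes[[g]] + 1 / sizes[[reference_label]]))
    (mean_rank[[g]] - mean_rank[[reference_label]]) / se
  }, numeric(1))
  p <- 2 * stats::pnorm(-abs(z))
  if (correct) p <- pmin(p * length(others), 1)
  data.frame(comparison = paste(others, "vs", reference_label),
             statistic = z, p_value = p, row.names = NULL)
}

# Pooled-variance t-tests of each group against the reference (ANOVA
# residual mean square, df = N - k), Holm-Sidak adjusted.
anova_holm_sidak_vs_reference <- function(groups, reference_label) {
  k <- length(groups)
  sizes <- lengths(groups)
  n <- sum(sizes)
  means <- vapply(groups, mean, numeric(1))
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) / (n - k)
  others <- setdiff(names(groups), reference_label)
  tstat <- vapply(others, function(g) {
    se <- sqrt(mse * (1 / sizes[[g]] + 1 / sizes[[reference_label]]))
    (means[[g]] - means[[reference_label]]) / se
  }, numeric(1))
  p <- 2 * stats::pt(-abs(tstat), df = n - k)
  data.frame(comparison = paste(others, "vs", reference_label),
             statistic = tstat, p_value = p_adjust_holm_sidak(p),
             row.names = NULL)
}

#' Normality-gated group comparison
#'
#' Applies the branch chosen by [normality_gate()]: two-group designs use
#' an unpaired t-test (parametric; equal variances, as established by the
#' gate) or a two-sided Mann-Whitney test; multi-group designs use
#' one-way ANOVA followed by Holm-Sidak-adjusted comparisons against the
#' reference group, or Kruskal-Wallis followed by Dunn's test against the
#' reference. All tests are two-sided. Contrasts designed as independent
#' experiments (e.g. a sleep-deprivation arm alongside a circadian
#' panel) should be passed as separate two-group sets so they are not
#' swept into the multiple-comparison correction.
#'
#' @param gs A [group_set()].
#' @param alpha Significance level for the `significant` flags.
#' @param alpha_gate Gate level passed to [normality_gate()].
#' @param gate Optional precomputed [normality_gate()] result.
#' @param correct For the nonparametric multi-group branch: adjust Dunn
#'   p-values over the comparisons versus the reference (default TRUE).
#' @return Object of class `comparison_result`: `branch`, `gate_details`,
#'   `tests_used`, `omnibus_p` (multi-group only), `comparisons`
#'   (data frame: comparison, statistic, p_value, significant).
#' @export
compare_groups <- function(gs, alpha = 0.05, alpha_gate = 0.05, gate = NULL,
                           correct = TRUE) {
  stopifnot(inherits(gs, "group_set"))
  if (any(lengths(gs$groups) == 0L)) stop("empty group")
  if (is.null(gate)) gate <- normality_gate(gs, alpha_gate)
  parametric <- gate$branch == "parametric"
  omnibus_p <- NA_real_
  if (gs$design == "two_group") {
    a <- gs$groups[[1L]]; b <- gs$groups[[2L]]
    if (parametric) {
      ht <- stats::t.test(a, b, var.equal = TRUE)
      tests <- "t-test (unpaired, equal variance)"
    } else {
      ht <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL))
      tests <- "Mann-Whitney"
    }
    comparisons <- data.frame(
      comparison = paste(names(gs$groups)[1L], "vs", names(gs$groups)[2L]),
      statistic = unname(ht$statistic), p_value = ht$p.value)
  } else {
    values <- unlist(gs$groups, use.names = FALSE)
    labels <- factor(rep(names(gs$groups), lengths(gs$groups)))
    if (parametric) {
      omnibus_p <- stats::anova(stats::aov(values ~ labels))[1L, "Pr(>F)"]
      comparisons <- anova_holm_sidak_vs_reference(gs$groups, gs$reference_label)
      tests <- "ANOVA + Holm-Sidak vs reference"
    } else {
      omnibus_p <- stats::kruskal.test(values, labels)$p.value
      comparisons <- dunn_vs_reference(gs$groups, gs$reference_label, correct)
      tests <- sprintf("Kruskal-Wallis + Dunn vs reference%s",
                       if (correct) "" else " (uncorrected)")
    }
  }
  comparisons$significant <- comparisons$p_value < alpha
  structure(list(branch = gate$branch, gate_details = gate,
                 tests_used = tests, omnibus_p = omnibus_p,
                 comparisons = comparisons, alpha = alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s branch: %s\n", x$branch, x$tests_used))
  if (!is.na(x$omnibus_p)) cat(sprintf("  omnibus p = %.4g\n", x$omnibus_p))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Dual-control conservative-P rule
#'
#' When an experimental group is compared separately against two controls
#' (e.g. GAL4 and UAS heterozygotes), only the numerically greatest
#' (most conservative) of the two p-values is reported, and a difference
#' is declared only when the group differs significantly from both
#' controls.
#'
#' @param p_vs_control_a,p_vs_control_b p-values (vectorized) in [0, 1].
#' @param alpha Significance level (strict: p must be below it).
#' @return Data frame: `reported_p = pmax(a, b)`, `significant` (both
#'   p-values strictly below `alpha`).
#' @export
conservative_p <- function(p_vs_control_a, p_vs_control_b, alpha = 0.05) {
  if (anyNA(p_vs_control_a) || anyNA(p_vs_control_b))
    stop("both control comparisons are required")
  if (any(c(p_vs_control_a, p_vs_control_b) < 0) ||
      any(c(p_vs_control_a, p_vs_control_b) > 1))
    stop("p-values must lie in [0, 1]")
  data.frame(reported_p = pmax(p_vs_control_a, p_vs_control_b),
             significant = p_vs_control_a < alpha & p_vs_control_b < alpha)
}

#' Normalize within experiments and pool
#'
#' Divides every value by the mean of its own experiment's control group
#' and concatenates across experiments, so each experiment's control
#' normalizes to mean 1 before pooling. Within-experiment value ratios
#' are unchanged.
#'
#' @param df Data frame with columns `value`, `group`, `experiment`.
#' @param control_label Group label of the control in every experiment.
#' @return `df` with an added `normalized` column.
#' @export
normalize_and_pool <- function(df, control_label) {
  need <- c("value", "group", "experiment")
  if (!all(need %in% names(df)))
    stop("df must contain columns: ", paste(need, collapse = ", "))
  parts <- split(df, df$experiment)
  out <- lapply(names(parts), function(e) {
    p <- parts[[e]]
    ctrl <- p$value[p$group == control_label]
    if (length(ctrl) == 0L)
      stop(sprintf("experiment '%s' has no '%s' control group", e, control_label))
    p$normalized <- normalize_to_group_mean(p$value, ctrl)
    p
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Relative expression by the delta-delta-Ct method
#'
#' Computes `dCt = Ct_target - Ct_reference` per sample, `ddCt = dCt -
#' mean(dCt of the control condition)`, and relative expression
#' `2^(-ddCt)`, normalized to a reference gene (Act79B role) and the
#' control condition. The control condition's geometric-mean expression
#' is 1 by construction (its arithmetic mean equals 1 exactly when
#' control dCt values are equal).
#'
#' @param table Data frame with columns `sample`, `condition`,
#'   `ct_target`, `ct_reference` (finite positive cycle thresholds).
#' @param control_condition Label of the control condition.
#' @return `table` with added `d_ct`, `dd_ct`, `rel_expression` columns.
#' @export
qpcr_ddct <- function(table, control_condition = "control") {
  need <- c("sample", "condition", "ct_target", "ct_reference")
  if (!all(need %in% names(table)))
    stop("Ct table must contain columns: ", paste(need, collapse = ", "))
  ct <- c(table$ct_target, table$ct_reference)
  if (anyNA(ct) || any(!is.finite(ct)) || any(ct <= 0))
    stop("Ct values must be finite and positive")
  if (!any(table$condition == control_condition))
    stop("no samples in the control condition '", control_condition, "'")
  table$d_ct <- table$ct_target - table$ct_reference
  ctrl_mean <- mean(table$d_ct[table$condition == control_condition])
  table$dd_ct <- table$d_ct - ctrl_mean
  table$rel_expression <- 2^(-table$dd_ct)
  table
}

#' Empirical type-I error of the gated two-group procedure
#'
#' Draws many null two-group datasets from a common distribution, runs
#' the full normality-gated comparison on each, and reports the fraction
#' rejected at `alpha`. Used to verify that branch switching preserves
#' the nominal error rate under both Gaussian and skewed (lognormal)
#' nulls.
#'
#' @param n_sim Number of simulated experiments.
#' @param n_per_group Sample size per group.
#' @param dist `"gaussian"` or `"lognormal"`.
#' @param alpha Nominal level.
#' @param seed RNG seed.
#' @return List: `rejection_rate`, `branch_counts` (table of branches
#'   taken), `n_sim`.
#' @export
gated_type1_error <- function(n_sim = 5000, n_per_group = 20,
                              dist = c("gaussian", "lognormal"),
                              alpha = 0.05, seed = 1) {
  dist <- match.arg(dist)
  draw <- switch(dist,
                 gaussian = function(n) stats::rnorm(n),
                 lognormal = function(n) stats::rlnorm(n))
  with_seed(seed, {
    rejected <- logical(n_sim)
    branch <- character(n_sim)
    for (i in seq_len(n_sim)) {
      gs <- group_set(list(a = draw(n_per_group), b = draw(n_per_group)))
      res <- compare_groups(gs, alpha = alpha)
      rejected[i] <- res$comparisons$significant[1L]
      branch[i] <- res$branch
    }
    list(rejection_rate = mean(rejected), branch_counts = table(branch),
         n_sim = n_sim)
  })
}
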