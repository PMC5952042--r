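# Group-comparison statistics in the form the field reports them: two-sided
# pairwise tests at alpha = 0.05, mean +/- SEM summaries, and a two-factor
# ANOVA with Bonferroni-corrected per-level post-tests for I/O curves.

sem <- function(x) stats::sd(x) / sqrt(length(x))

group_comparison <- function(metric_name, a, b, test, statistic, p_value,
                             alpha = 0.05) {
  structure(
    list(metric_name = metric_name,
         group_a_values = a, group_b_values = b,
         mean_sem_a = c(mean = mean(a), sem = sem(a)),
         mean_sem_b = c(mean = mean(b), sem = sem(b)),
         test = test, statistic = statistic, p_value = p_value,
         significant = p_value < alpha),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %.3g +/- %.3g vs %.3g +/- %.3g, %s p = %.4g%s\n",
              x$metric_name, x$mean_sem_a["mean"], x$mean_sem_a["sem"],
              x$mean_sem_b["mean"], x$mean_sem_b["sem"], x$test, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Two-tailed t test between two groups
#'
#' Student's (pooled-variance) t test by default, matching the conventional
#' reporting; Welch's correction available via `welch = TRUE`. Two groups
#' with zero variance and equal means give p = 1.
#'
#' @param a,b numeric vectors (n >= 2 each).
#' @param metric_name label carried into the result.
#' @param welch use Welch's unequal-variance t test.
#' @return A `group_comparison` (significant at p < 0.05, two-sided).
#' @export
two_tailed_t <- function(a, b, metric_name = "metric", welch = FALSE) {
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(group_comparison(metric_name, a, b, "t", 0, 1))
    stop("zero variance in both groups with unequal means")
  }
  ht <- stats::t.test(a, b, var.equal = !welch, alternative = "two.sided")
  group_comparison(metric_name, a, b, if (welch) "welch_t" else "t",
                   unname(ht$statistic), ht$p.value)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact for small samples (both n <= 8, no ties), normal approximation with
#' continuity and tie correction otherwise. All values tied gives p = 1.
#'
#' @param a,b numeric vectors (n >= 3 each).
#' @param metric_name label carried into the result.
#' @return A `group_comparison` with the U statistic.
#' @export
mann_whitney <- function(a, b, metric_name = "metric") {
  if (length(a) < 3 || length(b) < 3) stop("need n >= 3 per group")
  if (length(unique(c(a, b))) == 1)
    return(group_comparison(metric_name, a, b, "mann_whitney", NA_real_, 1))
  exact <- length(a) <= 8 && length(b) <= 8 &&
    !any(duplicated(c(a, b)))
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE,
                       alternative = "two.sided"))
  group_comparison(metric_name, a, b, "mann_whitney",
                   unname(ht$statistic), ht$p.value)
}

#' Two-factor ANOVA with Bonferroni post-tests
#'
#' Standard two-way decomposition (group, level, interaction) on a long
#' data frame, followed by per-level two-group t tests with Bonferroni
#' adjustment (`p_adj = min(1, p_raw * n_levels)`), the conventional analysis
#' for input/output curves compared between genotypes.
#'
#' @param data data frame with columns `group` (2 levels), `level` and
#'   `value`; at least 2 replicates per cell.
#' @return List with `anova_table`, `interaction_p`, `group_p`, and
#'   `post_tests` (data frame: `level`, `p_raw`, `p_adj`, `significant`).
#' @export
anova2_bonferroni <- function(data) {
  stopifnot(all(c("group", "level", "value") %in% names(data)))
  data$group <- factor(data$group)
  data$level <- factor(data$level)
  if (nlevels(data$group) < 2 || nlevels(data$level) < 2)
    stop("each factor needs at least two levels")
  fit <- stats::aov(value ~ group * level, data = data)
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  lev <- levels(data$level)
  post <- do.call(rbind, lapply(lev, function(l) {
    d <- data[data$level == l, ]
    gs <- split(d$value, d$group)
    p <- stats::t.test(gs[[1]], gs[[2]], var.equal = TRUE)$p.value
    data.frame(level = l, p_raw = p, p_adj = min(1, p * length(lev)))
  }))
  post$significant <- post$p_adj < 0.05
  list(anova_table = tab,
       interaction_p = tab[rn == "group:level", "Pr(>F)"],
       group_p = tab[rn == "group", "Pr(>F)"],
       post_tests = post)
}
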