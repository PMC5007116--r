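#' One-way ANOVA for a two-group (or k-group) comparison
#'
#' Classical one-way F test. For two groups of sizes n1, n2 the statistic
#' has df = (1, n1 + n2 - 2). Degenerate data with zero between- and
#' within-group variability return F = 0.
#'
#' @param values_by_group List of numeric vectors, one per group (each of
#'   length >= 2).
#' @return A `stat_result` list: `statistic`, `df` (length 2), `p_value`,
#'   `test_name`.
#' @export
anova_oneway <- function(values_by_group) {
  if (any(lengths(values_by_group) < 2)) {
    stop("each group needs at least 2 observations")
  }
  y <- unlist(values_by_group, use.names = FALSE)
  g <- factor(rep(seq_along(values_by_group), lengths(values_by_group)))
  # degenerate (zero-variance) groups are defined below, so the "perfect
  # fit" warning is suppressed
  tab <- suppressWarnings(stats::anova(stats::lm(y ~ g)))
  f <- tab[1, "F value"]
  df <- c(tab[1, "Df"], tab[2, "Df"])
  if (is.nan(f)) f <- 0 # 0/0: no variability anywhere
  stat_result(f, df, stats::pf(f, df[1], df[2], lower.tail = FALSE),
              "anova_oneway")
}

#' One-way ANOVA reconstructed from group summary statistics
#'
#' Computes the two-group F statistic from printed means, SDs and group
#' sizes by rebuilding the between- and within-group sums of squares:
#' identical to [anova_oneway()] on any dataset having exactly those
#' moments. Useful for checking published summary tables.
#'
#' @param mean1,sd1,n1 First group's mean, SD, size (n1 >= 2, sd1 >= 0).
#' @param mean2,sd2,n2 Second group's.
#' @return A `stat_result` (see [anova_oneway()]).
#' @export
anova_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  if (sd1 < 0 || sd2 < 0) stop("SDs must be non-negative")
  grand <- (n1 * mean1 + n2 * mean2) / (n1 + n2)
  ssb <- n1 * (mean1 - grand)^2 + n2 * (mean2 - grand)^2
  ssw <- (n1 - 1) * sd1^2 + (n2 - 1) * sd2^2
  df <- c(1, n1 + n2 - 2)
  f <- if (ssw == 0) {
    if (ssb == 0) 0 else Inf
  } else {
    (ssb / df[1]) / (ssw / df[2])
  }
  stat_result(f, df, stats::pf(f, df[1], df[2], lower.tail = FALSE),
              "anova_from_summary")
}

#' ANCOVA group effect with age as covariate
#'
#' Fits the general linear model `value ~ group + age` and reports the
#' type-III F test for the group term, df = (1, n - 3).
#'
#' @param values Numeric outcome vector.
#' @param group Two-level grouping factor (or coercible).
#' @param age Numeric covariate; must vary.
#' @return A `stat_result`.
#' @export
ancova_group <- function(values, group, age) {
  group <- factor(group)
  if (length(values) < 4) stop("need at least 4 subjects")
  if (stats::sd(age) == 0) stop("age does not vary")
  if (nlevels(group) < 2) stop("need two groups")
  if (stats::sd(values) == 0) { # constant outcome: nothing to explain
    return(stat_result(0, c(1, length(values) - 3), 1, "ancova_group"))
  }
  m <- stats::lm(values ~ group + age)
  if (any(is.na(stats::coef(m)))) stop("group and age are collinear")
  if (sum(stats::residuals(m)^2) < 1e-12 * sum(values^2)) {
    # covariate explains the outcome exactly: no group effect to test
    return(stat_result(0, c(1, length(values) - 3), 1, "ancova_group"))
  }
  a <- car::Anova(m, type = 3)
  f <- a["group", "F value"]
  df <- c(a["group", "Df"], a["Residuals", "Df"])
  if (is.nan(f)) f <- 0 # 0/0: constant outcome
  stat_result(f, df, stats::pf(f, df[1], df[2], lower.tail = FALSE),
              "ancova_group")
}

#' MANOVA across ROIs with age covariate (Wilks' lambda)
#'
#' Tests the group effect on the multivariate ROI response (regional BP_ND
#' values as a within-subject profile) with age as covariate, using Wilks'
#' lambda and its F approximation. A single-column input reduces exactly to
#' [ancova_group()].
#'
#' @param roi_matrix n_subjects x n_roi numeric matrix.
#' @param group Two-level grouping factor.
#' @param age Numeric covariate.
#' @return A `stat_result` with the approximate F as `statistic` and the
#'   Wilks lambda in `$lambda`.
#' @export
manova_rois <- function(roi_matrix, group, age) {
  roi_matrix <- as.matrix(roi_matrix)
  group <- factor(group)
  n <- nrow(roi_matrix)
  if (ncol(roi_matrix) == 1) {
    return(ancova_group(roi_matrix[, 1], group, age))
  }
  if (n <= ncol(roi_matrix) + 2) {
    stop("too few subjects for ", ncol(roi_matrix), " ROIs; need more ",
         "subjects than responses plus model terms")
  }
  # age first, so the (sequential) group term is the age-adjusted effect
  fit <- tryCatch(
    stats::manova(roi_matrix ~ age + group),
    error = function(e) stop("MANOVA failed (singular within-group ",
                             "covariance?): ", conditionMessage(e))
  )
  s <- summary(fit, test = "Wilks")$stats
  lam <- s["group", "Wilks"]
  if (!is.finite(lam)) {
    stop("singular within-group covariance; more subjects are needed")
  }
  out <- stat_result(s["group", "approx F"],
                     c(s["group", "num Df"], s["group", "den Df"]),
                     s["group", "Pr(>F)"], "manova_wilks")
  out$lambda <- unname(lam)
  out
}

#' Levene's test for homogeneity of variances
#'
#' Classical (mean-centered) Levene test: a one-way ANOVA on the absolute
#' deviations from group means. `center = "median"` gives the
#' Brown-Forsythe variant.
#'
#' @param values_by_group List of numeric vectors, one per group.
#' @param center `"mean"` (default, classical Levene) or `"median"`.
#' @return A `stat_result`.
#' @export
levene_test <- function(values_by_group, center = c("mean", "median")) {
  center <- match.arg(center)
  if (any(lengths(values_by_group) < 2)) {
    stop("each group needs at least 2 observations")
  }
  y <- unlist(values_by_group, use.names = FALSE)
  g <- factor(rep(seq_along(values_by_group), lengths(values_by_group)))
  a <- suppressWarnings(
    car::leveneTest(y, g, center = if (center == "mean") mean else median))
  f <- a[1, "F value"]
  if (is.nan(f)) f <- 0 # 0/0: all deviations equal
  stat_result(f, c(a[1, "Df"], a[2, "Df"]),
              stats::pf(f, a[1, "Df"], a[2, "Df"], lower.tail = FALSE),
              paste0("levene_", center))
}

#' Pearson correlation with two-sided t test
#'
#' @param x,y Numeric vectors (length >= 3, both non-constant).
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Pearson chi-square test for a 2x2 table
#'
#' Without continuity correction, df = 1.
#'
#' @param table 2x2 matrix of counts with all row and column margins > 0.
#' @return A `stat_result`.
#' @export
chi2_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("all row and column margins must be positive")
  }
  # small expected counts are fine here: the Pearson statistic itself is
  # the quantity of interest, so the approximation warning is suppressed
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  stat_result(unname(ct$statistic), unname(ct$parameter), ct$p.value,
              "chi2_2x2")
}

#' Bonferroni adjustment
#'
#' `adjusted = min(1, p * m)` for `m` planned comparisons; `m` may exceed
#' the number of supplied p-values.
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @param m Number of comparisons (default: `length(p_values)`).
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (m < 1) stop("m must be >= 1")
  if (m < length(p_values)) stop("m must be >= the number of p-values")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  pmin(1, p_values * m)
}

#' Two-group sample size (normal approximation)
#'
#' Per-group sample size for detecting a mean difference between two normal
#' populations with a two-sided level-`alpha` test:
#' \deqn{n = \lceil (z_{1-\alpha/2} + z_{power})^2 (\sigma_1^2 + \sigma_2^2)
#'   / (\mu_1 - \mu_2)^2 \rceil}
#' The normal approximation (rather than noncentral t) is deliberate — it
#' is the classical planning formula for this setting. Also returns the
#' approximate power achieved at the returned integer n.
#'
#' @param mu1,mu2 Group means (must differ).
#' @param sigma1,sigma2 Group SDs (> 0).
#' @param alpha Two-sided significance level in (0, 1); e.g. 0.01 for a
#'   Bonferroni-corrected 0.05 across five ROIs.
#' @param power Target power in (0, 1).
#' @return List with `n` (per group), `n_exact` (before ceiling),
#'   `achieved_power`.
#' @export
sample_size_two_groups <- function(mu1, mu2, sigma1, sigma2,
                                   alpha = 0.01, power = 0.80) {
  if (sigma1 <= 0 || sigma2 <= 0) stop("SDs must be positive")
  if (mu1 == mu2) stop("mu1 must differ from mu2 (otherwise n is infinite)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (power <= 0 || power >= 1) stop("power must lie in (0, 1)")
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  n_exact <- (za + zb)^2 * (sigma1^2 + sigma2^2) / (mu1 - mu2)^2
  n <- ceiling(n_exact)
  se <- sqrt((sigma1^2 + sigma2^2) / n)
  achieved <- stats::pnorm(abs(mu1 - mu2) / se - za)
  list(n = as.integer(n), n_exact = n_exact, achieved_power = achieved)
}

stat_result <- function(statistic, df, p_value, test_name) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), test_name = test_name),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: statistic = %.4g, df = (%s), p = %.4g\n",
              x$test_name, x$statistic,
              paste(format(x$df), collapse = ", "), x$p_value))
  invisible(x)
}
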