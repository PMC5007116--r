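test_that("one-way ANOVA matches hand-computed sums of squares", {
  expect_equal(anova_oneway(list(c(1, 2, 3), c(1, 2, 3)))$statistic, 0)

  # groups (1,2,3) vs (2,3,4): SSB = 1.5, SSW = 4 on 4 df -> F = 1.5
  a <- anova_oneway(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(a$statistic, 1.5, tolerance = 1e-12)
  expect_equal(a$df, c(1, 4))
  expect_equal(a$p_value, pf(1.5, 1, 4, lower.tail = FALSE))
  expect_error(anova_oneway(list(1, c(1, 2))), "at least 2")
})

test_that("ANOVA rejection rate sits in the expected band for the
           configured total-gray effect", {
  set.seed(202)
  rej <- mean(replicate(1000, {
    x <- rnorm(17, 0.14, 0.09)
    y <- rnorm(19, 0.17, 0.09)
    anova_oneway(list(x, y))$p_value < 0.05
  }))
  expect_gt(rej, 0.05)
  expect_lt(rej, 0.35)
})

test_that("summary-statistic ANOVA equals the data version on matched
           moments", {
  # equal printed means -> F = 0.00
  expect_equal(round(anova_from_summary(0.15, 0.07, 17,
                                        0.15, 0.07, 19)$statistic, 2), 0)
  # construct data with exactly the requested moments and compare
  make_group <- function(m, s, n) {
    z <- scale(seq_len(n))[, 1]
    m + s * z
  }
  set.seed(77)
  for (i in 1:100) {
    m1 <- runif(1, -1, 1); m2 <- runif(1, -1, 1)
    s1 <- runif(1, 0.05, 2); s2 <- runif(1, 0.05, 2)
    n1 <- sample(3:40, 1); n2 <- sample(3:40, 1)
    a_sum <- anova_from_summary(m1, s1, n1, m2, s2, n2)
    a_dat <- anova_oneway(list(make_group(m1, s1, n1),
                               make_group(m2, s2, n2)))
    expect_equal(a_sum$statistic, a_dat$statistic, tolerance = 1e-9)
    expect_equal(a_sum$df, a_dat$df)
  }
})

test_that("ANCOVA group test is consistent with one-way ANOVA when age is
           irrelevant", {
  set.seed(11)
  n <- 1000
  g <- rep(c("a", "b"), each = n / 2)
  age <- rnorm(n, 30, 5)
  y <- rnorm(n) + 0.2 * (g == "b")
  fc <- ancova_group(y, g, age)$statistic
  f1 <- anova_oneway(split(y, g))$statistic
  expect_lt(abs(fc - f1) / f1, 0.10)
  expect_equal(ancova_group(y, g, age)$df, c(1, n - 3))
  expect_error(ancova_group(y, g, rep(1, n)), "vary")
})

test_that("ANCOVA does not flag group when the outcome is pure age", {
  hits <- vapply(1:500, function(s) {
    set.seed(s)
    age <- rnorm(30, 30, 5)
    g <- sample(rep(c("a", "b"), 15))
    ancova_group(age, g, age + rnorm(30, 0, 1e-8))$p_value > 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("ANCOVA type-I error is calibrated under the null", {
  rej <- vapply(1:5000, function(s) {
    set.seed(10000 + s)
    g <- rep(c("a", "b"), each = 10)
    ancova_group(rnorm(20), g, rnorm(20))$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("MANOVA reduces to ANCOVA for one response and matches the
           determinant-ratio oracle", {
  set.seed(5)
  n <- 20
  g <- factor(rep(c("a", "b"), each = n / 2))
  age <- rnorm(n, 30, 4)
  y <- rnorm(n)
  uni <- manova_rois(matrix(y, ncol = 1), g, age)
  expect_equal(uni$statistic, ancova_group(y, g, age)$statistic,
               tolerance = 1e-9)

  Y <- matrix(rnorm(8 * 3), 8, 3)
  g8 <- factor(rep(c("a", "b"), each = 4))
  age8 <- rnorm(8, 30, 4)
  mv <- manova_rois(Y, g8, age8)
  expect_equal(mv$lambda, wilks_oracle(Y, g8, age8), tolerance = 1e-9)

  # identical groups: lambda ~ 1, F ~ 0
  Y2 <- rbind(matrix(rnorm(15), 5, 3), matrix(0, 5, 3))
  Y2[6:10, ] <- Y2[1:5, ]
  mv2 <- manova_rois(Y2, factor(rep(c("a", "b"), each = 5)),
                     c(1:5, 1:5) + 20)
  expect_equal(mv2$lambda, 1, tolerance = 1e-9)
  expect_lt(mv2$statistic, 1e-6)
})

test_that("Levene's test matches a hand oracle and is calibrated", {
  # shifted copies have equal spreads
  expect_equal(levene_test(list(c(1, 2, 5), c(11, 12, 15)))$statistic, 0,
               tolerance = 1e-12)
  # (0,10) vs (4,6): absolute deviations (5,5) vs (1,1); the statistic is
  # the one-way F on those deviations, whatever its numeric fate
  lv <- levene_test(list(c(0, 10), c(4, 6)))
  dev_f <- anova_oneway(list(c(5, 5), c(1, 1)))$statistic
  expect_equal(lv$statistic, dev_f, tolerance = 1e-6)
  # a case with non-degenerate deviations, F computed by hand:
  # |0,10,2 - 4| = (4,6,2), |4,6,5 - 5| = (1,1,0) -> F = 200/26
  lv2 <- levene_test(list(c(0, 10, 2), c(4, 6, 5)))
  expect_equal(lv2$statistic, 200 / 26, tolerance = 1e-9)
  expect_equal(lv2$df, c(1, 4))
  # equal-variance calibration at the study's group sizes
  rej <- vapply(1:5000, function(s) {
    set.seed(20000 + s)
    levene_test(list(rnorm(17), rnorm(19)))$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("Pearson correlation follows the closed form", {
  expect_equal(pearson_corr(1:10, 2 * (1:10))$r, 1)
  expect_equal(pearson_corr(1:10, -(1:10))$r, -1)
  pc <- pearson_corr(c(1, 2, 3), c(1, 3, 2))
  expect_equal(pc$r, 0.5, tolerance = 1e-12)
  t_stat <- 0.5 * sqrt((3 - 2) / (1 - 0.25))
  expect_equal(pc$p_value, 2 * pt(t_stat, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(pearson_corr(rep(1, 5), 1:5), "constant")
})

test_that("2x2 chi-square equals the closed form without continuity
           correction", {
  ch <- chi2_2x2(rbind(c(14, 3), c(16, 3)))
  expect_equal(round(ch$statistic, 2), 0.02)
  expect_equal(ch$df, 1)
  expect_equal(chi2_2x2(rbind(c(14, 3), c(14, 3)))$statistic, 0)
  set.seed(31)
  for (i in 1:20) {
    tab <- matrix(sample(1:30, 4, replace = TRUE), 2)
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    n <- sum(tab)
    closed <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(chi2_2x2(tab)$statistic, closed, tolerance = 1e-12)
  }
  expect_error(chi2_2x2(rbind(c(0, 0), c(1, 2))), "margins")
})

test_that("Bonferroni adjustment caps at one and sets the per-ROI level", {
  expect_equal(bonferroni_adjust(0.01, 5), 0.05)
  expect_equal(bonferroni_adjust(0.5, 5), 1.0)
  # overall 0.05 across five ROIs -> per-test alpha 0.01
  expect_equal(0.05 / 5, 0.01)
  expect_error(bonferroni_adjust(c(0.1, 0.2), 1), ">=")
  expect_error(bonferroni_adjust(1.2, 2), "\\[0, 1\\]")
})

test_that("sample-size routine reproduces the planning formula", {
  got <- sample_size_two_groups(0.07, 0.18, 0.10, 0.08,
                                alpha = 0.01, power = 0.80)
  expect_equal(got$n, 16L)
  # monotone in alpha
  looser <- sample_size_two_groups(0.07, 0.18, 0.10, 0.08,
                                   alpha = 0.05, power = 0.80)
  expect_lt(looser$n, got$n)
  # doubling both sigmas quadruples n before ceiling
  big <- sample_size_two_groups(0.07, 0.18, 0.20, 0.16,
                                alpha = 0.01, power = 0.80)
  expect_equal(big$n_exact / got$n_exact, 4, tolerance = 1e-12)
  # numeric power-inversion oracle: smallest integer n whose analytic
  # power reaches the target
  pow <- function(n) {
    se <- sqrt((0.10^2 + 0.08^2) / n)
    pnorm(abs(0.07 - 0.18) / se - qnorm(1 - 0.01 / 2))
  }
  n_oracle <- which(vapply(1:100, pow, numeric(1)) >= 0.80)[1]
  expect_equal(got$n, n_oracle)
  expect_gte(got$achieved_power, 0.80)
  # monotone in effect size and sd
  wide <- sample_size_two_groups(0.07, 0.30, 0.10, 0.08, alpha = 0.01)
  expect_lt(wide$n, got$n)
  expect_error(sample_size_two_groups(0.1, 0.1, 1, 1), "differ")
})
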