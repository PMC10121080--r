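# Frozen external oracle values: scipy.stats.normaltest on the same data.
scipy_x <- c(10.609434, 7.920032, 11.500902, 11.881129, 6.09793, 7.395641,
             10.255681, 9.367515, 9.966398, 8.293912, 11.758796, 11.555584,
             10.132061, 12.254482, 10.935019, 8.281415, 10.737502, 8.082235,
             11.756901, 9.900148, 9.630275, 8.638141, 12.445083, 9.690941,
             9.143344, 9.295733, 11.064618, 10.730888, 10.825465, 10.861642)
scipy_y <- c(15.079227, 1.963774, 1.80436, 1.417623, 4.449464, 6.707175,
             2.481447, 1.388015, 1.405531, 4.574394, 4.926375, 4.197644,
             1.596146, 3.273072, 2.984251, 3.23798, 5.458331, 3.25072,
             4.679217, 2.869286, 3.425665, 4.504291, 0.847279, 2.10489,
             1.865822)

test_that("the omnibus normality statistic matches an external implementation", {
  r <- dagostino_pearson(scipy_x)
  expect_equal(r$k2, 1.9577805740, tolerance = 1e-8)
  expect_equal(r$p, 0.3757278176, tolerance = 1e-8)
  ry <- dagostino_pearson(scipy_y)
  expect_gt(ry$k2, 30)           # strongly lognormal: decisively rejected
  expect_lt(ry$p, 1e-6)
  expect_error(dagostino_pearson(rnorm(10)), "n >= 20")
})

test_that("the normality test is calibrated and powered", {
  set.seed(31)
  rej <- mean(replicate(600, dagostino_pearson(rnorm(50))$p < 0.05))
  expect_lt(abs(rej - 0.05), 0.025)
  power <- mean(replicate(200, dagostino_pearson(rlnorm(50, 0, 0.8))$p < 0.05))
  expect_gte(power, 0.9)
})

test_that("Welch CIs reproduce printed group-summary comparisons", {
  # PPI v50 (ms): (41.28 +/- 1.50, n 17) vs (45.79 +/- 1.46, n 16)
  r <- welch_t(list(mean = 41.28, sem = 1.50, n = 17),
               list(mean = 45.79, sem = 1.46, n = 16))
  expect_equal(r$conf_low, -8.80, tolerance = 0.005)
  expect_equal(r$conf_high, -0.23, tolerance = 0.05)
  # input resistance (MOhm): (167.5 +/- 14.9, n 9) vs (223.0 +/- 25.6, n 10)
  r2 <- welch_t(list(mean = 167.5, sem = 14.9, n = 9),
                list(mean = 223.0, sem = 25.6, n = 10))
  expect_equal(r2$conf_low, -118.9, tolerance = 0.001)
  # identical summaries: difference 0, p = 1
  s <- list(mean = 5, sem = 1, n = 10)
  r3 <- welch_t(s, s)
  expect_equal(r3$estimate, 0)
  expect_equal(r3$p, 1)
  expect_error(welch_t(list(mean = 1, sem = 0, n = 5),
                       list(mean = 1, sem = 0, n = 5)), "zero variance")
})

test_that("Welch from summaries equals Welch from raw samples", {
  set.seed(8)
  x <- rnorm(12, 10, 3); y <- rnorm(15, 12, 2)
  raw <- welch_t(x, y)
  summ <- welch_t(list(mean = mean(x), sem = sd(x) / sqrt(12), n = 12),
                  list(mean = mean(y), sem = sd(y) / sqrt(15), n = 15))
  expect_equal(raw$p, summ$p, tolerance = 1e-12)
  expect_equal(raw$conf_low, summ$conf_low, tolerance = 1e-12)
  base <- t.test(x, y)   # cross-check against the reference implementation
  expect_equal(raw$p, base$p.value, tolerance = 1e-12)
  expect_equal(c(raw$conf_low, raw$conf_high), unname(base$conf.int),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("group CIs use the exact t quantile", {
  ci <- group_ci(38.71, 1.42, 17)
  expect_equal(round(ci, 2), c(35.70, 41.72))
  expect_equal(group_ci(5, 0, 10), c(5, 5))
  expect_equal(qt(0.975, 16), t_quantile_quadrature(0.975, 16),
               tolerance = 1e-6)
})

test_that("Hodges-Lehmann estimate is the median pairwise difference", {
  r <- mann_whitney(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$estimate, -1)   # median of the 9 pairwise differences
  same <- mann_whitney(c(1, 5, 9, 13), c(1, 5, 9, 13))
  expect_equal(same$p, 1)
})

test_that("exact Mann-Whitney p equals the enumeration oracle", {
  set.seed(14)
  for (n1 in 2:6) for (n2 in 2:6) {
    x <- round(rnorm(n1, 0, 2), 1)   # rounding produces occasional ties
    y <- round(rnorm(n2, 0.5, 2), 1)
    r <- mann_whitney(x, y)
    expect_true(r$exact)
    expect_equal(r$p, mw_enumeration_oracle(x, y), tolerance = 1e-12,
                 label = paste("n1", n1, "n2", n2))
  }
})

test_that("exact Mann-Whitney CI agrees with the reference implementation", {
  set.seed(5)
  x <- rnorm(8); y <- rnorm(9, 0.8)   # continuous: no ties
  r <- mann_whitney(x, y)
  w <- wilcox.test(x, y, conf.int = TRUE, exact = TRUE)
  expect_equal(r$p, w$p.value, tolerance = 1e-12)
  expect_equal(c(r$conf_low, r$conf_high), unname(w$conf.int),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(r$estimate, unname(w$estimate), tolerance = 1e-12)
})

test_that("the large-sample branch applies the tie-corrected approximation", {
  set.seed(9)
  x <- round(rnorm(20, 0, 1), 0); y <- round(rnorm(20, 0.7, 1), 0)
  r <- mann_whitney(x, y)
  expect_false(r$exact)
  w <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(r$p, w$p.value, tolerance = 1e-9)
})

test_that("chi-squared independence reproduces the cohort block table", {
  tab <- matrix(c(7, 10, 2, 0), 2)   # rows: groups; cols: blocked yes/no
  r <- chi2_independence(tab)
  expect_equal(round(r$chi2, 1), 2.5)
  expect_equal(round(r$p, 2), 0.12)
  expect_equal(r$df, 1)
  expect_equal(round(as.vector(t(r$expected)), 2),
               c(8.05, 0.95, 8.95, 1.05))
  # invariances: transpose and row swap
  expect_equal(chi2_independence(t(tab))$chi2, r$chi2)
  expect_equal(chi2_independence(tab[2:1, ])$chi2, r$chi2)
  # perfect independence
  expect_equal(chi2_independence(matrix(5, 2, 2))$chi2, 0)
  expect_error(chi2_independence(matrix(c(0, 0, 1, 2), 2)), "marginal")
})

test_that("balanced additive designs have zero interaction", {
  d <- expand.grid(genotype = c("WT", "KO"), treatment = c("ctl", "ttx"),
                   rep = 1:5)
  d$y <- 2 * (d$genotype == "KO") + 3 * (d$treatment == "ttx")
  a <- two_way_anova(d, "y", c("genotype", "treatment"), posthoc = FALSE)
  # purely additive construction: the interaction captures no variance
  expect_equal(a$terms$sum_sq[a$terms$term == "genotype:treatment"], 0,
               tolerance = 1e-12)
  expect_gt(a$terms$sum_sq[a$terms$term == "genotype"], 0)
})

test_that("the CS mixed model equals RM-ANOVA on complete balanced data", {
  set.seed(2)
  d <- expand.grid(subject = paste0("s", 1:12),
                   ipi = factor(c(10, 20, 40, 80)))
  d$genotype <- ifelse(as.integer(sub("s", "", d$subject)) <= 6, "WT", "KO")
  d$y <- rnorm(nrow(d)) + as.numeric(d$ipi) / 40 + (d$genotype == "KO") * 0.5
  a1 <- two_way_anova(d, "y", "genotype", within = "ipi",
                      subject = "subject", model = "rm_anova")
  a2 <- suppressMessages(
    two_way_anova(d, "y", "genotype", within = "ipi", subject = "subject",
                  model = "cs_mixed_reml"))
  expect_equal(a1$model, "rm_anova")
  expect_equal(a2$model, "cs_mixed_reml")
  for (term in a1$terms$term) {
    expect_equal(a2$terms$F[a2$terms$term == term],
                 a1$terms$F[a1$terms$term == term], tolerance = 1e-6,
                 label = term)
  }
  # missing cells route to the mixed model automatically
  a3 <- suppressMessages(two_way_anova(d[-c(3, 17), ], "y", "genotype",
                                       within = "ipi", subject = "subject"))
  expect_equal(a3$model, "cs_mixed_reml")
  expect_error(two_way_anova(d[d$genotype == "WT", ], "y", "genotype",
                             within = "ipi", subject = "subject"),
               "fewer than 2 levels")
})

test_that("Bonferroni post-tests use the within-factor comparison count", {
  set.seed(4)
  d <- expand.grid(subject = paste0("s", 1:10),
                   ipi = factor(c(20, 40, 80)))
  d$genotype <- ifelse(as.integer(sub("s", "", d$subject)) <= 5, "WT", "KO")
  d$y <- rnorm(nrow(d))
  a <- two_way_anova(d, "y", "genotype", within = "ipi",
                     subject = "subject")
  expect_equal(nrow(a$posthoc), 3)
  expect_equal(a$posthoc$p_bonferroni,
               pmin(1, 3 * a$posthoc$p_raw))
})

test_that("bonferroni caps and scales as specified", {
  expect_equal(bonferroni(0.01, 20), 0.2)
  expect_equal(bonferroni(0.2, 10), 1)
  expect_equal(bonferroni(c(0.03, 0.2), 2), c(0.06, 0.4))
  expect_equal(bonferroni(0.04, 1), 0.04)
  expect_error(bonferroni(c(0.1, 0.2), 1), "m must be")
})

test_that("compare_groups routes small samples to the nonparametric branch", {
  set.seed(6)
  v <- c(rnorm(10, 40, 4), rnorm(10, 44, 4))
  g <- rep(c("WT", "KO"), each = 10)
  r <- compare_groups(v, g, group_levels = c("WT", "KO"))
  expect_match(r$test, "Mann-Whitney")
  expect_match(r$note, "n < 20")
  v2 <- c(rnorm(25, 40, 4), rnorm(25, 44, 4))
  g2 <- rep(c("WT", "KO"), each = 25)
  r2 <- compare_groups(v2, g2, group_levels = c("WT", "KO"))
  expect_match(r2$test, "Welch")
})
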