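# The study's statistics layer: normality testing, Welch t with CI of the
# difference, exact Mann-Whitney with Hodges-Lehmann CI, chi-squared
# independence, two-way (repeated-measures) ANOVA with a compound-symmetry
# mixed-model variant, and Bonferroni post-tests. Group differences are
# oriented as group1 - group2 (WT - KO in the standard design).

stat_result <- function(test, estimate, conf_low, conf_high, statistic, df,
                        p, exact = FALSE) {
  tibble::tibble(test = test, estimate = estimate, conf_low = conf_low,
                 conf_high = conf_high, statistic = statistic, df = df,
                 p = p, exact = exact)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness (D'Agostino 1970) and kurtosis
#' (Anscombe & Glynn 1983) into `K2 = Z_skew^2 + Z_kurt^2`, referred to a
#' chi-squared distribution with 2 df. Requires `n >= 20`; smaller samples
#' should be routed to the nonparametric branch instead (see
#' [compare_groups()]).
#'
#' @param x Numeric sample.
#' @return List with `k2`, `p`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 20)
    stop("D'Agostino-Pearson test needs n >= 20; ",
         "use the nonparametric branch for smaller samples", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  # skewness
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z_s <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  z_k <- ((1 - 2 / (9 * a)) -
            ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z_s^2 + z_k^2
  list(k2 = k2, p = stats::pchisq(k2, 2, lower.tail = FALSE),
       z_skew = z_s, z_kurt = z_k, n = n)
}

#' 95 % confidence interval of a group mean from its summary
#'
#' `mean +/- t(0.975, n-1) * SEM`.
#'
#' @param mean,sem,n Group mean, standard error of the mean, sample size.
#' @param conf_level Confidence level.
#' @return Numeric `c(low, high)`.
#' @export
group_ci <- function(mean, sem, n, conf_level = 0.95) {
  stopifnot(n >= 2)
  tq <- stats::qt(1 - (1 - conf_level) / 2, n - 1)
  c(mean - tq * sem, mean + tq * sem)
}

#' Welch's unpaired t test with CI of the difference
#'
#' Accepts raw samples or `(mean, sem, n)` summaries (as `list(mean =, sem
#' =, n =)`), so printed group summaries can be re-analyzed. Uses the
#' Welch-Satterthwaite degrees of freedom; the estimate is oriented as
#' group1 - group2.
#'
#' @param sample1,sample2 Numeric vectors, or lists with elements `mean`,
#'   `sem`, `n`.
#' @param conf_level Confidence level for the CI of the difference.
#' @return A one-row `stat_result` tibble (test, estimate, conf_low,
#'   conf_high, statistic, df, p, exact).
#' @export
welch_t <- function(sample1, sample2, conf_level = 0.95) {
  summ <- function(s) {
    if (is.list(s)) {
      stopifnot(all(c("mean", "sem", "n") %in% names(s)), s$n >= 2)
      list(m = s$mean, se2 = s$sem^2, n = s$n)
    } else {
      stopifnot(length(s) >= 2)
      list(m = mean(s), se2 = stats::var(s) / length(s), n = length(s))
    }
  }
  a <- summ(sample1); b <- summ(sample2)
  if (a$se2 == 0 && b$se2 == 0)
    stop("both samples have zero variance", call. = FALSE)
  se2 <- a$se2 + b$se2
  df <- se2^2 / (a$se2^2 / (a$n - 1) + b$se2^2 / (b$n - 1))
  est <- a$m - b$m
  tstat <- est / sqrt(se2)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  stat_result("Welch t (two-tailed)", est,
              est - tq * sqrt(se2), est + tq * sqrt(se2),
              tstat, df, 2 * stats::pt(-abs(tstat), df))
}

# Exact permutation distribution of the group-1 midrank sum, with ties
# handled as-is: dynamic-programming enumeration over all C(n1+n2, n1)
# assignments using integer-doubled midrank scores.
ranksum_exact_dist <- function(scores2, n1) {
  smax <- sum(scores2)
  # counts[j, s+1] = number of size-(j-1) subsets with score sum s
  counts <- matrix(0, n1 + 1, smax + 1)
  counts[1, 1] <- 1
  for (sc in scores2) {
    # RHS is evaluated before assignment, so each score enters at most once
    counts[2:(n1 + 1), (sc + 1):(smax + 1)] <-
      counts[2:(n1 + 1), (sc + 1):(smax + 1)] +
      counts[1:n1, 1:(smax + 1 - sc)]
  }
  counts[n1 + 1, ]
}

#' Mann-Whitney test with Hodges-Lehmann estimate and CI
#'
#' Two-sided Mann-Whitney U test. For `n1 + n2 <= 25` the p value is exact,
#' from the full permutation distribution of the rank sum (enumerated with
#' mid-rank tied scores as they stand); above that a normal approximation
#' with mid-ranks and the tie-corrected variance is used. The location
#' estimate is the Hodges-Lehmann median of all pairwise differences
#' (sample1 - sample2); the CI comes from the ordered pairwise differences
#' at the exact U quantiles (normal-approximation quantiles in the large-
#' sample branch).
#'
#' @param sample1,sample2 Numeric samples (n >= 2 each).
#' @param conf_level Confidence level.
#' @return A one-row `stat_result` tibble with `exact` indicating the
#'   branch.
#' @export
mann_whitney <- function(sample1, sample2, conf_level = 0.95) {
  x <- sample1[is.finite(sample1)]; y <- sample2[is.finite(sample2)]
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2, n2 >= 2)
  diffs <- sort(as.vector(outer(x, y, "-")))
  hl <- stats::median(diffs)
  alpha2 <- (1 - conf_level) / 2
  exact <- (n1 + n2) <= 25
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])          # midrank sum of sample 1
  u <- w - n1 * (n1 + 1) / 2        # Mann-Whitney U of sample 1
  if (exact) {
    scores2 <- as.integer(round(2 * r))
    cnt <- ranksum_exact_dist(scores2, n1)
    tot <- sum(cnt)
    w2 <- as.integer(round(2 * w))
    lo <- sum(cnt[seq_len(w2 + 1)]) / tot           # P(W <= w)
    hi <- sum(cnt[(w2 + 1):length(cnt)]) / tot      # P(W >= w)
    p <- min(1, 2 * min(lo, hi))
    qu <- stats::qwilcox(alpha2, n1, n2)
    if (qu == 0) qu <- 1
    ci <- c(diffs[qu], diffs[n1 * n2 - qu + 1])
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(r)
    sig2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(tie_tab^3 - tie_tab) /
         ((n1 + n2) * (n1 + n2 - 1)))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    k <- max(1, floor(mu + stats::qnorm(alpha2) * sqrt(sig2)))
    ci <- c(diffs[k], diffs[n1 * n2 - k + 1])
  }
  stat_result(paste0("Mann-Whitney (two-tailed",
                     if (exact) ", exact" else "", ")"),
              hl, ci[1], ci[2], u, NA_real_, p, exact = exact)
}

#' Chi-squared test of independence (uncorrected)
#'
#' Pearson chi-squared on a contingency table of counts, without continuity
#' correction — the convention needed to reproduce textbook 2 x 2 values
#' from small cohorts.
#'
#' @param table Matrix of non-negative integer counts (e.g. 2 x 2).
#' @return List with `chi2`, `df`, `p`, `expected`.
#' @export
chi2_independence <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0) || any(abs(m - round(m)) > 1e-9))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero marginal total", call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, expected = res$expected)
}

#' Two-way (repeated-measures) ANOVA with a compound-symmetry mixed variant
#'
#' For a between x within design with complete data, the classical
#' repeated-measures ANOVA decomposition (`aov` with a subject error
#' stratum). When cells are missing — or on request — a mixed model with a
#' compound-symmetry covariance (random subject intercept) is fitted by
#' REML and tested with Satterthwaite degrees of freedom; on complete
#' balanced data the two give identical F statistics. For two crossed
#' between factors (no `within`), an ordinary two-way ANOVA. Bonferroni
#' post-tests compare the groups at each level of the second factor, with
#' the multiplier equal to the number of comparisons.
#'
#' @param data Data frame.
#' @param dv,between,within,subject Column names (strings); `within` and
#'   `subject` are `NULL` for a purely between-subjects design.
#' @param model `"auto"` (repeated-measures ANOVA when complete,
#'   mixed model when cells are missing), `"rm_anova"`, or
#'   `"cs_mixed_reml"`.
#' @param posthoc Compute the Bonferroni post-test table.
#' @return List of class `anova_result`: `terms` (tibble of F, df, p per
#'   effect), `posthoc` (or `NULL`), `model` (the kind used).
#' @export
two_way_anova <- function(data, dv, between, within = NULL, subject = NULL,
                          model = c("auto", "rm_anova", "cs_mixed_reml"),
                          posthoc = TRUE) {
  model <- match.arg(model)
  data <- as.data.frame(data)
  f2 <- if (is.null(within)) between[2] else within
  f1 <- between[1]
  for (v in c(f1, f2)) {
    data[[v]] <- factor(data[[v]])
    if (nlevels(data[[v]]) < 2)
      stop("factor '", v, "' has fewer than 2 levels", call. = FALSE)
  }
  data <- data[stats::complete.cases(data[, c(dv, f1, f2)]), ]
  fml_fixed <- stats::as.formula(paste(dv, "~", f1, "*", f2))

  if (is.null(within)) {
    fit <- do.call(stats::aov, list(fml_fixed, data = data))
    tab <- summary(fit)[[1]]
    terms_tbl <- anova_terms_from_aov(tab)
    used <- "anova"
    emm_fit <- fit
  } else {
    if (is.null(subject))
      stop("repeated-measures design needs a subject column", call. = FALSE)
    data[[subject]] <- factor(data[[subject]])
    complete <- all(table(data[[subject]], data[[f2]]) == 1)
    use_mixed <- model == "cs_mixed_reml" || (model == "auto" && !complete)
    if (model == "rm_anova" && !complete)
      stop("cells are missing: use the cs_mixed_reml model", call. = FALSE)
    if (use_mixed) {
      old <- options(contrasts = c("contr.sum", "contr.poly"))
      on.exit(options(old), add = TRUE)
      fml <- stats::as.formula(paste(dv, "~", f1, "*", f2, "+ (1|", subject,
                                     ")"))
      fit <- do.call(lmerTest::lmer, list(fml, data = data, REML = TRUE))
      if (inherits(fit, "try-error"))
        stop("REML fit failed", call. = FALSE)
      tab <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
      terms_tbl <- tibble::tibble(term = rownames(tab),
                                  F = tab[["F value"]],
                                  df1 = tab[["NumDF"]], df2 = tab[["DenDF"]],
                                  p = tab[["Pr(>F)"]])
      used <- "cs_mixed_reml"
      emm_fit <- fit
    } else {
      fml <- stats::as.formula(paste(dv, "~", f1, "*", f2, "+ Error(",
                                     subject, ")"))
      fit <- do.call(stats::aov, list(fml, data = data))
      s <- summary(fit)
      btab <- s[["Error: " %+% subject]][[1]]
      wtab <- s[["Error: Within"]][[1]]
      terms_tbl <- rbind(anova_terms_from_aov(btab),
                         anova_terms_from_aov(wtab))
      used <- "rm_anova"
      emm_fit <- fit
    }
  }

  post <- NULL
  if (posthoc) {
    emm <- emmeans::emmeans(emm_fit,
                            stats::as.formula(paste0("~", f1, "|", f2)),
                            data = data)
    ctr <- emmeans::contrast(emm, "pairwise")
    m <- nlevels(data[[f2]])
    sm <- summary(ctr, adjust = "none")
    cf <- stats::confint(ctr, level = 0.95, adjust = "none")
    post <- tibble::tibble(level = as.character(sm[[f2]]),
                           contrast = as.character(sm$contrast),
                           estimate = sm$estimate,
                           conf_low = cf$lower.CL, conf_high = cf$upper.CL,
                           p_raw = sm$p.value,
                           p_bonferroni = bonferroni(sm$p.value, m))
  }
  structure(list(terms = terms_tbl, posthoc = post, model = used),
            class = "anova_result")
}

`%+%` <- function(a, b) paste0(a, b)

anova_terms_from_aov <- function(tab) {
  rn <- trimws(rownames(tab))
  keep <- rn != "Residuals"
  df_res <- tab$Df[!keep]
  tibble::tibble(term = rn[keep], F = tab[["F value"]][keep],
                 df1 = tab$Df[keep], df2 = df_res,
                 p = tab[["Pr(>F)"]][keep],
                 sum_sq = tab[["Sum Sq"]][keep])
}

#' @export
print.anova_result <- function(x, ...) {
  cat("<anova_result> model:", x$model, "\n")
  print(as.data.frame(x$terms), digits = 4)
  invisible(x)
}

#' Bonferroni correction
#'
#' `p_adj = min(1, m * p)` with an explicit comparison count `m` (which must
#' be at least the number of p values supplied).
#'
#' @param p Raw p values.
#' @param m Number of comparisons in the family.
#' @return Adjusted p values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < length(p)) stop("m must be >= length(p)", call. = FALSE)
  pmin(1, m * p)
}

#' Compare two groups the way the study's decision tree does
#'
#' Both groups are screened for normality (D'Agostino-Pearson when both
#' n >= 20; smaller samples are routed to the nonparametric branch with a
#' note); normally distributed data get Welch's t test, anything else the
#' Mann-Whitney test. The estimate is oriented group1 - group2 following
#' the order of `group_levels`.
#'
#' @param values Numeric measurements.
#' @param group Group label per measurement (2 levels).
#' @param group_levels Optional explicit level order (reference first).
#' @param alpha Normality screening level.
#' @return One-row tibble: data_structure, test, estimate, conf_low,
#'   conf_high, statistic, df, p, exact, note.
#' @export
compare_groups <- function(values, group, group_levels = NULL, alpha = 0.05) {
  group <- as.character(group)
  lev <- group_levels %||% unique(group)
  stopifnot(length(lev) == 2)
  x <- values[group == lev[1]]; y <- values[group == lev[2]]
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  note <- NA_character_
  if (length(x) >= 20 && length(y) >= 20) {
    normal <- dagostino_pearson(x)$p > alpha && dagostino_pearson(y)$p > alpha
  } else {
    normal <- FALSE
    note <- "n < 20: normality not assessable, nonparametric branch used"
  }
  res <- if (normal) welch_t(x, y) else mann_whitney(x, y)
  tibble::tibble(data_structure = if (normal) "normal" else "non-normal",
                 res, note = note)
}
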