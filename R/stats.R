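#' Lilliefors-corrected Kolmogorov-Smirnov normality test
#'
#' KS distance between the sample and a normal distribution with mean and SD
#' estimated from the same sample. Because parameters are estimated, the
#' classical KS null distribution does not apply; the p-value is computed from
#' a seeded Monte-Carlo null (standard-normal samples of the same size,
#' default 10,000 replicates). The screening convention used downstream calls
#' a sample acceptably normal when `p >= 0.01`.
#'
#' @param x Numeric sample, `n >= 5`, non-degenerate.
#' @param n_mc Monte-Carlo replicates for the null distribution.
#' @param seed Seed for the Monte-Carlo null.
#' @return One-row tibble: `statistic` (D), `p_value`, `n`, `n_mc`.
#' @export
lilliefors_ks <- function(x, n_mc = 10000, seed = 1) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 5) abort("need n >= 5")
  if (sd(x) == 0) abort("sample has zero variance")
  d_stat <- function(v) {
    m <- length(v)
    z <- sort((v - mean(v)) / sd(v))
    pz <- pnorm(z)
    i <- seq_len(m)
    max(i / m - pz, pz - (i - 1) / m)
  }
  D <- d_stat(x)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_mc), function(b) d_stat(rnorm(n)) >= D, logical(1)))
  })
  tibble(statistic = D, p_value = (exceed + 1) / (n_mc + 1),
         n = n, n_mc = n_mc)
}

#' Levene's test for homogeneity of variances (classical, mean-centred)
#'
#' The classical Levene statistic: absolute deviations from the group means
#' are submitted to a one-way ANOVA; W is the resulting F statistic on
#' `(k - 1, N - k)` degrees of freedom. (The median-centred Brown-Forsythe
#' variant is deliberately not used.)
#'
#' @param data Data frame in long form.
#' @param value,group Columns with the measurements and group labels
#'   (tidy-eval).
#' @return One-row tibble: `statistic` (W), `df1`, `df2`, `p_value`.
#' @export
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 10), y = rnorm(20))
#' levene_test(d, y, g)
levene_test <- function(data, value, group) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  if (nlevels(g) < 2) abort("need >= 2 groups")
  if (any(table(g) < 2)) abort("each group needs n >= 2")
  z <- abs(v - ave(v, g, FUN = mean))
  k <- nlevels(g)
  N <- length(v)
  zbar <- mean(z)
  zg <- tapply(z, g, mean)
  ng <- tabulate(g)
  ssb <- sum(ng * (zg - zbar)^2)
  ssw <- sum((z - ave(z, g, FUN = mean))^2)
  df1 <- k - 1
  df2 <- N - k
  W <- if (ssw == 0 && ssb == 0) 0 else (ssb / df1) / (ssw / df2)
  p <- if (ssw == 0 && ssb == 0) 1 else pf(W, df1, df2, lower.tail = FALSE)
  tibble(statistic = W, df1 = df1, df2 = df2, p_value = p)
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition on independent groups.
#'
#' @inheritParams levene_test
#' @return One-row tibble: `statistic` (F), `df1`, `df2`, `p_value`,
#'   `ms_within`.
#' @export
oneway_anova <- function(data, value, group) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  if (nlevels(g) < 2) abort("need >= 2 groups")
  if (any(table(g) < 2)) abort("each group needs n >= 2")
  ng <- tabulate(g)
  mg <- tapply(v, g, mean)
  grand <- mean(v)
  ssb <- sum(ng * (mg - grand)^2)
  ssw <- sum((v - ave(v, g, FUN = mean))^2)
  df1 <- nlevels(g) - 1
  df2 <- length(v) - nlevels(g)
  if (ssw == 0 && ssb == 0) {
    return(tibble(statistic = 0, df1 = df1, df2 = df2, p_value = 1,
                  ms_within = 0))
  }
  F <- (ssb / df1) / (ssw / df2)
  tibble(statistic = F, df1 = df1, df2 = df2,
         p_value = pf(F, df1, df2, lower.tail = FALSE),
         ms_within = ssw / df2)
}

#' One-way ANOVA from printed group summaries
#'
#' Reconstructs the classical F test from per-group means, SDs and sizes -
#' the arithmetic needed to audit published summary tables without raw data.
#'
#' @param means,sds Numeric vectors of group means and SDs.
#' @param n Group sizes (scalar recycled, or vector).
#' @return One-row tibble: `statistic`, `df1`, `df2`, `p_value`, `ms_within`.
#' @export
#' @examples
#' oneway_anova_summary(c(39.916, 41.254, 39.967), c(1.275, 1.251, 1.180), 21)
oneway_anova_summary <- function(means, sds, n) {
  k <- length(means)
  stopifnot(k >= 2, length(sds) == k, all(sds >= 0))
  n <- rep_len(n, k)
  if (any(n < 2)) abort("each group needs n >= 2")
  N <- sum(n)
  grand <- sum(n * means) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum((n - 1) * sds^2)
  df1 <- k - 1
  df2 <- N - k
  if (ssw == 0 && ssb == 0) {
    return(tibble(statistic = 0, df1 = df1, df2 = df2, p_value = 1,
                  ms_within = 0))
  }
  F <- (ssb / df1) / (ssw / df2)
  tibble(statistic = F, df1 = df1, df2 = df2,
         p_value = pf(F, df1, df2, lower.tail = FALSE),
         ms_within = ssw / df2)
}

bonferroni_pairs <- function(labels, means, dfw, msw, ns, alpha) {
  k <- length(labels)
  m <- k * (k - 1) / 2
  grid <- expand.grid(i = seq_len(k), j = seq_len(k))
  grid <- grid[grid$i != grid$j, ]
  purrr::map_dfr(seq_len(nrow(grid)), function(r) {
    i <- grid$i[r]; j <- grid$j[r]
    diff <- means[i] - means[j]
    se <- sqrt(msw * (1 / ns[i] + 1 / ns[j]))
    p_un <- if (se == 0) {
      if (diff == 0) 1 else 0
    } else {
      2 * pt(-abs(diff / se), dfw)
    }
    crit <- qt(1 - alpha / (2 * m), dfw)
    tibble(group_1 = labels[i], group_2 = labels[j],
           mean_difference = diff,
           ci_low = diff - crit * se, ci_high = diff + crit * se,
           p_value = p_un, adjusted_p = min(1, m * p_un), sem = se)
  })
}

#' Bonferroni-corrected pairwise comparisons after one-way ANOVA
#'
#' All ordered group pairs with mean differences, standard errors from the
#' pooled within-group mean square, t-based confidence intervals at the
#' Bonferroni-adjusted level `alpha / m` (`m` = number of unordered pairs),
#' and Bonferroni-adjusted p-values `min(1, m * p)`.
#'
#' @inheritParams levene_test
#' @param alpha Family-wise error level (default 0.05).
#' @return Tibble with one row per ordered pair: `group_1`, `group_2`,
#'   `mean_difference`, `ci_low`, `ci_high`, `p_value`, `adjusted_p`, `sem`.
#' @export
bonferroni_pairwise <- function(data, value, group, alpha = 0.05) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  if (nlevels(g) < 2) abort("need >= 2 groups")
  if (any(table(g) < 2)) abort("each group needs n >= 2")
  ng <- tabulate(g)
  mg <- as.numeric(tapply(v, g, mean))
  ssw <- sum((v - ave(v, g, FUN = mean))^2)
  dfw <- length(v) - nlevels(g)
  bonferroni_pairs(levels(g), mg, dfw, ssw / dfw, ng, alpha)
}

#' Bonferroni pairwise comparisons from printed group summaries
#'
#' @inheritParams oneway_anova_summary
#' @param labels Group labels.
#' @param alpha Family-wise error level.
#' @return As [bonferroni_pairwise()].
#' @export
#' @examples
#' bonferroni_pairwise_summary(c("FBP", "SAFIRE", "ADMIRE"),
#'                             c(39.916, 41.254, 39.967),
#'                             c(1.275, 1.251, 1.180), 21)
bonferroni_pairwise_summary <- function(labels, means, sds, n, alpha = 0.05) {
  k <- length(labels)
  stopifnot(k >= 2, length(means) == k, length(sds) == k)
  n <- rep_len(n, k)
  dfw <- sum(n) - k
  msw <- sum((n - 1) * sds^2) / dfw
  bonferroni_pairs(labels, means, dfw, msw, n, alpha)
}

#' Paired t test
#'
#' Thin wrapper over [stats::t.test()] for paired samples, returned tidy.
#'
#' @param a,b Paired numeric vectors.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `mean_difference`.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  if (sd(d) == 0) {
    # zero-variance differences: identical pairs give t = 0, p = 1; an exact
    # constant shift is infinitely significant in the limit
    return(tibble(statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                  df = length(d) - 1,
                  p_value = if (mean(d) == 0) 1 else 0,
                  mean_difference = mean(d)))
  }
  ht <- t.test(a, b, paired = TRUE)
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, mean_difference = unname(ht$estimate))
}

#' Wilcoxon signed-rank test (tie-corrected normal approximation)
#'
#' Matched-pairs signed-rank test with the conventions of the major
#' commercial statistics packages: zero differences are dropped, tied
#' absolute differences get midranks, and the p-value uses the normal
#' approximation with tie-corrected variance
#' `n(n+1)(2n+1)/24 - sum(t^3 - t)/48` and no continuity correction.
#'
#' @param a,b Paired numeric vectors; at least 5 non-zero differences.
#' @return One-row tibble: `statistic` (W, sum of positive-difference ranks),
#'   `z`, `p_value`, `n_effective`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) abort("all differences are zero: no informative pairs")
  if (n < 5) abort("need >= 5 non-zero differences")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  EW <- n * (n + 1) / 4
  ties <- table(r)
  varW <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(ties^3 - ties) / 48
  if (varW <= 0) abort("degenerate variance (all differences tied to zero)")
  z <- (W - EW) / sqrt(varW)
  tibble(statistic = W, z = z, p_value = 2 * pnorm(-abs(z)), n_effective = n)
}

#' Partial eta squared from an F statistic
#'
#' Effect size `SS_effect / (SS_effect + SS_error)`, recovered from the F
#' statistic and its degrees of freedom as `F*df1 / (F*df1 + df2)`.
#'
#' @param f F statistic (>= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom (> 0).
#' @return Scalar in `[0, 1)`.
#' @export
#' @examples
#' partial_eta_sq(1000.731, 8, 160)
partial_eta_sq <- function(f, df1, df2) {
  stopifnot(is_scalar_number(f), f >= 0, df1 > 0, df2 > 0)
  f * df1 / (f * df1 + df2)
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' One-way repeated-measures ANOVA over `k` within-subject conditions.
#' Sphericity is screened by Mauchly's test on the orthonormal contrast space
#' of the condition covariance matrix; when violated (`p < 0.05`) the
#' Greenhouse-Geisser epsilon shrinks both degrees of freedom. Epsilon is
#' always reported; for `k = 2` it is exactly 1. Partial eta squared uses the
#' uncorrected sums of squares (the correction rescales both df equally and
#' leaves the F statistic itself unchanged).
#'
#' @param data Long data frame with one row per subject x condition.
#' @param value,subject,condition Columns (tidy-eval).
#' @param sphericity_alpha Threshold below which the GG correction is applied.
#' @return Object of class `ctnps_rmanova`; see [tidy.ctnps_rmanova()].
#' @export
rm_anova_gg <- function(data, value, subject, condition,
                        sphericity_alpha = 0.05) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  s <- factor(rlang::eval_tidy(rlang::enquo(subject), data))
  cond <- factor(rlang::eval_tidy(rlang::enquo(condition), data))
  k <- nlevels(cond)
  n <- nlevels(s)
  if (k < 2) abort("need >= 2 conditions")
  if (length(v) != n * k || any(table(s, cond) != 1)) {
    abort("need a complete subject x condition grid (one row per cell)")
  }
  Y <- matrix(NA_real_, n, k)
  Y[cbind(as.integer(s), as.integer(cond))] <- v
  grand <- mean(Y)
  m_cond <- colMeans(Y)
  m_subj <- rowMeans(Y)
  ss_cond <- n * sum((m_cond - grand)^2)
  ss_subj <- k * sum((m_subj - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  F <- (ss_cond / df1) / (ss_err / df2)
  # Greenhouse-Geisser epsilon from the contrast-projected covariance
  S <- cov(Y)
  M <- qr.Q(qr(stats::contr.helmert(k)))      # orthonormal k x (k-1)
  Sc <- t(M) %*% S %*% M
  lam_tr <- sum(diag(Sc))
  eps <- if (k == 2) 1 else lam_tr^2 / (df1 * sum(Sc * t(Sc)))
  eps <- min(1, max(eps, 1 / df1))
  # Mauchly's sphericity test (chi-square approximation)
  mauchly_p <- NA_real_
  if (k > 2 && n > k) {
    detSc <- det(Sc)
    if (detSc > 0) {
      Wst <- detSc / (lam_tr / df1)^df1
      ff <- (2 * df1^2 + df1 + 2) / (6 * df1)
      chi2 <- -(n - 1 - ff) * log(Wst)
      mauchly_p <- pchisq(chi2, df1 * (df1 + 1) / 2 - 1, lower.tail = FALSE)
    } else {
      mauchly_p <- 0
    }
  }
  gg_applied <- is.finite(mauchly_p) && mauchly_p < sphericity_alpha
  df1_used <- if (gg_applied) eps * df1 else df1
  df2_used <- if (gg_applied) eps * df2 else df2
  structure(list(
    statistic = F, df1 = df1_used, df2 = df2_used,
    df1_uncorrected = df1, df2_uncorrected = df2,
    p_value = pf(F, df1_used, df2_used, lower.tail = FALSE),
    epsilon_gg = eps, gg_applied = gg_applied, mauchly_p = mauchly_p,
    partial_eta_sq = ss_cond / (ss_cond + ss_err),
    n_subjects = n, n_conditions = k,
    ss = c(condition = ss_cond, subject = ss_subj, error = ss_err)
  ), class = "ctnps_rmanova")
}

#' @export
print.ctnps_rmanova <- function(x, ...) {
  cat(sprintf(
    "Repeated-measures ANOVA: F(%.4g, %.4g) = %.4g, p = %.4g\n",
    x$df1, x$df2, x$statistic, x$p_value))
  cat(sprintf("  GG epsilon = %.3f (%s), partial eta^2 = %.3f\n",
              x$epsilon_gg,
              if (x$gg_applied) "applied" else "not applied",
              x$partial_eta_sq))
  invisible(x)
}

#' Tidy a repeated-measures ANOVA fit
#'
#' @param x A `ctnps_rmanova` object.
#' @param ... Unused.
#' @return One-row tibble with the test statistic, degrees of freedom
#'   (corrected if the GG correction was applied), p-value, epsilon and
#'   partial eta squared.
#' @export
tidy.ctnps_rmanova <- function(x, ...) {
  tibble(statistic = x$statistic, df1 = x$df1, df2 = x$df2,
         p_value = x$p_value, epsilon_gg = x$epsilon_gg,
         gg_applied = x$gg_applied, partial_eta_sq = x$partial_eta_sq)
}

#' @rdname tidy.ctnps_rmanova
#' @export
glance.ctnps_rmanova <- function(x, ...) {
  tibble(n_subjects = x$n_subjects, n_conditions = x$n_conditions,
         mauchly_p = x$mauchly_p, p_value = x$p_value)
}

#' Descriptive summary of an ordinal score sample
#'
#' Median, quartiles (SPSS-style weighted-average quantiles, type 6),
#' interquartile range, mean and SD.
#'
#' @param scores Numeric vector, `n >= 2`.
#' @return One-row tibble: `median`, `q1`, `q3`, `iqr`, `mean`, `sd`, `n`.
#' @export
#' @examples
#' summarize_ordinal(c(rep(9, 20), 8))
summarize_ordinal <- function(scores) {
  if (length(scores) < 2) abort("need n >= 2 (SD undefined otherwise)")
  q <- unname(quantile(scores, c(0.25, 0.5, 0.75), type = 6))
  tibble(median = q[2], q1 = q[1], q3 = q[3], iqr = q[3] - q[1],
         mean = mean(scores), sd = sd(scores), n = length(scores))
}
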