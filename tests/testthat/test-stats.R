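test_that("Lilliefors statistic agrees with the reference implementation", {
  withr::with_seed(1, x <- rnorm(50))
  ours <- lilliefors_ks(x, n_mc = 200, seed = 2)
  ref <- nortest::lillie.test(x)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
})

test_that("Lilliefors test separates normal from non-normal samples", {
  withr::with_seed(3, x <- rnorm(1000))
  expect_gt(lilliefors_ks(x, n_mc = 500, seed = 1)$p_value, 0.1)
  e <- qexp(seq(0.0025, 0.9975, length.out = 200))    # skewed sample
  expect_lt(lilliefors_ks(e, n_mc = 500, seed = 1)$p_value, 0.01)
  u <- qunif(seq(0.0005, 0.9995, length.out = 1000))  # flat sample
  expect_lt(lilliefors_ks(u, n_mc = 500, seed = 1)$p_value, 0.01)
  expect_error(lilliefors_ks(rep(1, 10)), "zero variance")
  expect_error(lilliefors_ks(rnorm(4)), "n >= 5")
})

test_that("classical Levene matches car::leveneTest with mean centring", {
  withr::with_seed(7, {
    d <- data.frame(g = rep(c("a", "b", "c"), each = 15),
                    y = c(rnorm(15, sd = 1), rnorm(15, sd = 2), rnorm(15, sd = 1)))
  })
  ours <- levene_test(d, y, g)
  ref <- car::leveneTest(y ~ factor(g), data = d, center = mean)
  expect_equal(ours$statistic, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(ours$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("Levene detects gross variance differences and passes identical groups", {
  d0 <- data.frame(g = rep(c("a", "b"), each = 6), y = rep(c(1, 2, 3), 4))
  r0 <- levene_test(d0, y, g)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  withr::with_seed(11, {
    d1 <- data.frame(g = rep(c("a", "b"), each = 50),
                     y = c(rnorm(50, sd = 1), rnorm(50, sd = 5)))
  })
  expect_lt(levene_test(d1, y, g)$p_value, 0.01)
})

test_that("Levene type-I error is near nominal under equal variances", {
  rej <- withr::with_seed(13, {
    mean(replicate(2000, {
      d <- data.frame(g = rep(c("a", "b"), each = 10), y = rnorm(20))
      levene_test(d, y, g)$p_value < 0.05
    }))
  })
  tol <- 3 * sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(rej - 0.05), tol + 0.01)   # Levene is only asymptotically exact
})

test_that("summary-statistic ANOVA reproduces the published significance pattern", {
  ref <- reference_roi_summary()
  for (d in c(1.0, 0.9, 0.7)) {
    gm <- dplyr::filter(ref, tissue == "GM", dose == d)
    wm <- dplyr::filter(ref, tissue == "WM", dose == d)
    expect_lt(oneway_anova_summary(gm$mean_hu, gm$sd_hu, 21)$p_value, 0.005)
    expect_gt(oneway_anova_summary(wm$mean_hu, wm$sd_hu, 21)$p_value, 0.05)
  }
  gm0 <- dplyr::filter(ref, tissue == "GM", dose == 1.0)
  expect_equal(round(oneway_anova_summary(gm0$mean_hu, gm0$sd_hu, 21)$p_value, 3),
               0.001)
})

test_that("one-way ANOVA agrees with the squared two-sample t on two groups", {
  withr::with_seed(17, {
    d <- data.frame(g = rep(c("a", "b"), each = 12), y = rnorm(24))
  })
  ours <- oneway_anova(d, y, g)
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(ours$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(ours$p_value, tt$p.value, tolerance = 1e-10)
  same <- data.frame(g = rep(c("a", "b"), each = 3), y = rep(c(1, 2, 3), 2))
  r <- oneway_anova(same, y, g)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("raw-data ANOVA and summary-statistic ANOVA coincide", {
  withr::with_seed(19, {
    d <- data.frame(g = rep(c("a", "b", "c"), each = 21), y = rnorm(63, sd = 1.3))
  })
  ours <- oneway_anova(d, y, g)
  summ <- oneway_anova_summary(tapply(d$y, d$g, mean), tapply(d$y, d$g, sd), 21)
  expect_equal(ours$statistic, summ$statistic, tolerance = 1e-12)
  expect_equal(ours$p_value, summ$p_value, tolerance = 1e-12)
})

test_that("Bonferroni pairwise differences are antisymmetric and conservative", {
  withr::with_seed(23, {
    d <- data.frame(g = rep(c("a", "b", "c"), each = 10), y = rnorm(30))
  })
  pw <- bonferroni_pairwise(d, y, g)
  expect_equal(nrow(pw), 6)
  ab <- pw$mean_difference[pw$group_1 == "a" & pw$group_2 == "b"]
  ba <- pw$mean_difference[pw$group_1 == "b" & pw$group_2 == "a"]
  expect_equal(ab, -ba)
  expect_true(all(pw$ci_low <= pw$mean_difference & pw$mean_difference <= pw$ci_high))
  expect_true(all(pw$adjusted_p >= pw$p_value))
  # property over repeated draws
  ok <- withr::with_seed(29, {
    all(replicate(300, {
      dd <- data.frame(g = rep(c("a", "b", "c"), each = 5), y = rnorm(15))
      p <- bonferroni_pairwise(dd, y, g)
      all(p$adjusted_p >= p$p_value - 1e-12) && all(p$adjusted_p <= 1)
    }))
  })
  expect_true(ok)
  same <- data.frame(g = rep(c("a", "b"), each = 4), y = rep(1:4, 2))
  ps <- bonferroni_pairwise(same, y, g)
  expect_true(all(ps$mean_difference == 0))
  expect_true(all(ps$adjusted_p == 1))
})

test_that("pairwise mean differences reproduce the published comparison table", {
  ref <- reference_roi_summary()
  gm0 <- dplyr::filter(ref, tissue == "GM", dose == 1.0)
  pw <- bonferroni_pairwise_summary(gm0$method, gm0$mean_hu, gm0$sd_hu, 21)
  fbp_saf <- pw$mean_difference[pw$group_1 == "FBP" & pw$group_2 == "SAFIRE"]
  fbp_adm <- pw$mean_difference[pw$group_1 == "FBP" & pw$group_2 == "ADMIRE"]
  expect_equal(round(fbp_saf, 3), -1.338)
  expect_equal(round(fbp_adm, 3), -0.051)
  expect_lt(pw$adjusted_p[pw$group_1 == "FBP" & pw$group_2 == "SAFIRE"], 0.05)
  expect_gt(pw$adjusted_p[pw$group_1 == "FBP" & pw$group_2 == "ADMIRE"], 0.9)
})

test_that("paired t handles degenerate and shifted pairs", {
  a <- c(1, 2, 3, 4, 5)
  r0 <- paired_t(a, a)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  rs <- paired_t(a + 2, a)
  expect_equal(rs$p_value, 0)
  withr::with_seed(31, {
    x <- rnorm(20); y <- x + rnorm(20, mean = 1)
  })
  ours <- paired_t(x, y)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value)
})

test_that("Wilcoxon signed-rank follows the drop-zeros midrank convention", {
  expect_error(wilcoxon_signed_rank(1:10, 1:10), "no informative pairs")
  expect_error(wilcoxon_signed_rank(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 6)), ">= 5")
  # published score multisets, maximally concordant pairing: 10 unit
  # differences among 21 pairs
  orig <- sort(c(rep(9, 20), 8), decreasing = TRUE)
  red <- sort(c(rep(9, 10), rep(8, 11)), decreasing = TRUE)
  res <- wilcoxon_signed_rank(orig, red)
  expect_equal(res$n_effective, 10L)
  expect_lt(res$p_value, 0.01)
  oracle <- wilcoxon_exact_oracle(orig, red)
  expect_equal(res$statistic, oracle$W)
  expect_lt(abs(res$p_value - oracle$p), 0.005)
})

test_that("normal-approximation p matches exact enumeration for small n", {
  diffs <- withr::with_seed(37, {
    replicate(60, {
      n <- sample(10:12, 1)
      a <- rnorm(n)
      b <- a + rnorm(n, mean = 0.3)
      res <- wilcoxon_signed_rank(a, b)
      oracle <- wilcoxon_exact_oracle(a, b)
      c(res$statistic - oracle$W, res$p_value - oracle$p)
    })
  })
  expect_true(all(diffs[1, ] == 0))            # identical W statistic
  expect_lt(mean(abs(diffs[2, ])), 0.04)       # p close to exact on average
  expect_lt(max(abs(diffs[2, ])), 0.08)        # normal-approximation accuracy
})

test_that("Wilcoxon p is invariant to adding a constant to every pair", {
  withr::with_seed(41, {
    a <- rnorm(15)
    b <- a + rnorm(15, 0.5)
  })
  r1 <- wilcoxon_signed_rank(a, b)
  r2 <- wilcoxon_signed_rank(a + 100, b + 100)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$statistic, r2$statistic)
})

test_that("paired tests hold their nominal type-I error under the null", {
  rates <- withr::with_seed(43, {
    res <- replicate(2000, {
      x <- rnorm(20)
      y <- rnorm(20)
      c(paired_t(x, y)$p_value < 0.05,
        wilcoxon_signed_rank(x, y)$p_value < 0.05)
    })
    rowMeans(res)
  })
  tol <- 3 * sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(rates[1] - 0.05), tol)
  expect_lt(abs(rates[2] - 0.05), tol + 0.01)  # normal approximation slack
})

test_that("partial eta squared reproduces the worked example and the SS identity", {
  expect_equal(round(partial_eta_sq(1000.731, 8, 160), 3), 0.980)
  expect_equal(partial_eta_sq(0, 4, 40), 0)
  # sums-of-squares oracle on a small repeated-measures design
  withr::with_seed(47, {
    n <- 12; k <- 4
    subj <- rnorm(n)
    cond <- c(0, 1, 2, 0.5)
    d <- expand.grid(subject = 1:n, condition = 1:k)
    d$y <- subj[d$subject] + cond[d$condition] + rnorm(n * k, sd = 0.8)
  })
  fit <- rm_anova_gg(d, y, subject, condition)
  ss <- fit$ss
  expect_equal(fit$partial_eta_sq, ss["condition"] / (ss["condition"] + ss["error"]),
               ignore_attr = TRUE)
  expect_equal(partial_eta_sq(fit$statistic, fit$df1_uncorrected,
                              fit$df2_uncorrected),
               fit$partial_eta_sq, tolerance = 1e-12)
})

test_that("repeated-measures ANOVA and GG epsilon behave across structures", {
  # compound symmetry: epsilon near 1
  eps <- withr::with_seed(53, {
    n <- 100; k <- 4
    subj <- rnorm(n, sd = 2)
    d <- expand.grid(subject = 1:n, condition = 1:k)
    d$y <- subj[d$subject] + rnorm(n * k)
    rm_anova_gg(d, y, subject, condition)$epsilon_gg
  })
  expect_gt(eps, 0.95)
  expect_lte(eps, 1)
  # k = 2 forces epsilon = 1
  d2 <- withr::with_seed(59, {
    d <- expand.grid(subject = 1:10, condition = 1:2)
    d$y <- rnorm(20)
    d
  })
  expect_identical(rm_anova_gg(d2, y, subject, condition)$epsilon_gg, 1)
  # a strong condition shift is detected
  d3 <- withr::with_seed(61, {
    d <- expand.grid(subject = 1:15, condition = 1:3)
    d$y <- rnorm(45, sd = 0.3) + ifelse(d$condition == 2, 3, 0)
    d
  })
  fit3 <- rm_anova_gg(d3, y, subject, condition)
  expect_lt(fit3$p_value, 0.001)
  expect_gt(fit3$partial_eta_sq, 0.5)
  expect_error(rm_anova_gg(d3[-1, ], y, subject, condition), "complete")
  td <- tidy(fit3)
  expect_true(all(c("statistic", "epsilon_gg", "partial_eta_sq") %in% names(td)))
  expect_equal(glance(fit3)$n_subjects, 15)
})

test_that("ordinal summaries match a naive sort-based oracle", {
  s <- summarize_ordinal(c(rep(9, 20), 8))
  expect_equal(s$median, 9)
  expect_equal(s$iqr, 0)
  expect_equal(round(s$mean, 2), 8.95)
  expect_equal(round(s$sd, 2), 0.22)
  expect_error(summarize_ordinal(7), "n >= 2")
  withr::with_seed(67, {
    for (i in 1:20) {
      x <- sample(1:10, sample(5:30, 1), replace = TRUE)
      s <- summarize_ordinal(x)
      xs <- sort(x)
      expect_equal(s$median, quantile(xs, 0.5, type = 6, names = FALSE))
      expect_equal(s$mean, sum(xs) / length(xs))
      expect_equal(s$sd, sqrt(sum((xs - mean(xs))^2) / (length(xs) - 1)))
    }
  })
})
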