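test_that("exact collinear data give the exact regression line", {
  x <- c(1, 2, 3, 4, 5, 7, 9)
  fit <- suppressWarnings(fit_volume_regression(x, 2 * x + 1))
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_lt(fit$p_value, 1e-12)
  expect_error(fit_volume_regression(c(1, 2), c(1, 2)), "3 points")
  expect_error(fit_volume_regression(rep(2, 5), rnorm(5)), "constant")
})

test_that("the confidence band contains the fitted line", {
  set.seed(5)
  x <- runif(40, 0, 100)
  y <- 1.5 * x + rnorm(40, sd = 8)
  fit <- fit_volume_regression(x, y)
  expect_true(all(fit$ci_band$lower <= fit$ci_band$fit + 1e-12))
  expect_true(all(fit$ci_band$upper >= fit$ci_band$fit - 1e-12))
  expect_equal(fit$r_squared, fit$r^2)
})

test_that("regression is equivariant under common rescaling", {
  set.seed(6)
  x <- runif(30, 10, 90)
  y <- 0.8 * x + rnorm(30, sd = 5)
  f1 <- fit_volume_regression(x, y)
  f2 <- fit_volume_regression(10 * x, 10 * y)
  expect_equal(f2$slope, f1$slope, tolerance = 1e-10)
  expect_equal(f2$r, f1$r, tolerance = 1e-12)
  expect_equal(f2$p_value, f1$p_value, tolerance = 1e-9)
})

test_that("Shapiro-Wilk rejects uniform data and accepts its contract", {
  set.seed(11)
  rejected <- vapply(1:200, function(i) {
    shapiro_wilk(runif(200))$p < 0.05
  }, logical(1))
  expect_gte(mean(rejected), 0.95)
  expect_error(shapiro_wilk(c(1, 1, 1, 1)), "constant")
  expect_error(shapiro_wilk(c(1, 2)), "n >= 3")
})

test_that("Levene's test has ~5% type-I error under equal variances", {
  set.seed(12)
  rejected <- vapply(1:400, function(i) {
    levene(rnorm(30), rnorm(30))$p < 0.05
  }, logical(1))
  expect_gt(mean(rejected), 0.01)
  expect_lt(mean(rejected), 0.12)
  expect_error(levene(rep(1, 5), rep(2, 5)), "constant")
})

test_that("Wilcoxon signed-rank: all-positive n = 6 gives p = 0.03125", {
  p <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6, 7), rep(0, 6))
  expect_equal(as.numeric(p), 0.03125)
  expect_true(attr(p, "exact"))
})

test_that("exact Wilcoxon matches full sign enumeration for n <= 10", {
  set.seed(13)
  for (n in 5:10) {
    for (rep in 1:5) {
      a <- round(rnorm(n), 1)  # rounding induces occasional ties
      b <- round(rnorm(n), 1)
      if (all(a == b)) next
      expect_equal(as.numeric(wilcoxon_signed_rank(a, b)),
                   wilcoxon_enumeration_p(a, b),
                   tolerance = 1e-12,
                   label = sprintf("n=%d rep=%d", n, rep))
    }
  }
})

test_that("exact Wilcoxon agrees with the reference implementation when tie-free", {
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(6:20, 1)
    a <- rnorm(n); b <- rnorm(n)
    ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value
    expect_equal(as.numeric(wilcoxon_signed_rank(a, b)), ref,
                 tolerance = 1e-12)
  }
})

test_that("symmetric differences give p near 1 and zero differences fail", {
  p <- wilcoxon_signed_rank(c(-2, -1, 1, 2, -3, 3), rep(0, 6))
  expect_equal(as.numeric(p), 1)
  expect_error(wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3)), "zero")
})

test_that("the large-sample Wilcoxon approximation tracks the exact p", {
  set.seed(15)
  a <- rnorm(30, 0.3); b <- rnorm(30)
  p_exact <- wilcoxon_signed_rank(a, b, exact_limit = 30L)
  p_approx <- wilcoxon_signed_rank(a, b, exact_limit = 5L)
  expect_false(attr(p_approx, "exact"))
  expect_equal(as.numeric(p_approx), as.numeric(p_exact), tolerance = 0.02)
})

test_that("paired t matches the textbook formula", {
  set.seed(16)
  for (rep in 1:50) {
    n <- sample(4:15, 1)
    a <- rnorm(n); b <- rnorm(n)
    d <- a - b
    t_stat <- mean(d) / (sd(d) / sqrt(n))
    p_ref <- 2 * pt(-abs(t_stat), n - 1)
    expect_equal(as.numeric(paired_t(a, b)), p_ref, tolerance = 1e-12)
  }
  # exactly mean-zero differences -> t = 0, p = 1
  a <- c(1, 2, 3, 4); b <- c(2, 1, 4, 3)
  expect_equal(as.numeric(paired_t(a, b)), 1)
})

test_that("paired Cohen's d is mean over SD of the differences", {
  d <- cohens_d_paired(c(1, 3), c(0, 0))
  expect_equal(as.numeric(d), 2 / sqrt(2), tolerance = 1e-10)
  expect_equal(round(as.numeric(d), 4), 1.4142)
  expect_equal(attr(d, "magnitude"), "large")
  # differences {1, 2, -1, 1, 1}: mean 0.8, SD ~1.10 -> d ~0.73, medium
  expect_equal(attr(cohens_d_paired(c(1, 2, -1, 1, 1), rep(0, 5)),
                    "magnitude"),
               "medium")
  expect_error(cohens_d_paired(c(1, 2, 3), c(0, 1, 2)), "zero SD")
})

test_that("Holm-Bonferroni step-down gives the published thresholds", {
  out <- holm_bonferroni(c(0.013, 0.32), alpha = 0.05)
  expect_equal(out$threshold, c(0.025, 0.05))
  expect_equal(out$reject, c(TRUE, FALSE))

  none <- holm_bonferroni(c(1, 1, 1))
  expect_false(any(none$reject))

  single <- holm_bonferroni(0.04, alpha = 0.05)
  expect_equal(single$threshold, 0.05)
  expect_true(single$reject)

  # rejection stops at the first failure even if later p are tiny enough
  # for their own thresholds
  out2 <- holm_bonferroni(c(0.030, 0.049, 0.001), alpha = 0.05)
  expect_equal(out2$reject, c(FALSE, FALSE, TRUE))
})

test_that("Holm rejects at least as much as plain Bonferroni", {
  set.seed(17)
  for (rep in 1:50) {
    m <- sample(2:6, 1)
    p <- runif(m)^2
    holm <- holm_bonferroni(p, 0.05)
    bonf <- p <= 0.05 / m
    expect_true(all(holm$reject >= bonf))
    # and agrees with the reference adjusted p-values
    expect_equal(holm$reject, p.adjust(p, "holm") <= 0.05 + 1e-12)
  }
})

test_that("the gate picks the paired t for clean normal data, Wilcoxon for heavy tails", {
  set.seed(18)
  chosen_normal <- vapply(1:150, function(i) {
    base <- rnorm(30)
    cmp <- compare_modalities(base + rnorm(30, 0, 0.5),
                              base + rnorm(30, 0, 0.5),
                              rnorm(30, 40, 10), rnorm(30, 40, 10))
    cmp$dsc$chosen_test
  }, character(1))
  expect_gt(mean(chosen_normal == "PAIRED_T"), 0.7)  # ~ joint gate pass rate

  chosen_heavy <- vapply(1:100, function(i) {
    cmp <- compare_modalities(rt(40, df = 1), rnorm(40),
                              rnorm(40, 40, 10), rnorm(40, 40, 10))
    cmp$dsc$chosen_test
  }, character(1))
  expect_gte(mean(chosen_heavy == "WILCOXON"), 0.9)
})

test_that("identical paired groups yield no rejections after Holm", {
  set.seed(19)
  dsc <- runif(20)
  hd <- rnorm(20, 40, 10)
  cmp <- compare_modalities(dsc, dsc, hd, hd)
  expect_false(cmp$dsc$significant)
  expect_false(cmp$hd$significant)
  expect_equal(cmp$dsc$test_p, 1)
  expect_equal(cmp$dsc$cohens_d, 0)
})

test_that("length-mismatched samples are rejected", {
  expect_error(compare_modalities(runif(5), runif(6), rnorm(6), rnorm(6)),
               "paired")
})
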