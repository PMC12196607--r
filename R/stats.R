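#' Linear regression of FLAIR volume on Cho/NAA >= 2X volume
#'
#' Ordinary least squares with the 95% confidence band for the mean
#' regression line, plus the Pearson correlation and the two-tailed
#' p-value for a non-zero slope.
#'
#' @param x predictor volumes (cc), e.g. Cho/NAA >= 2X.
#' @param y response volumes (cc), e.g. T2-FLAIR hyperintensity.
#' @param conf_level confidence level of the mean-response band.
#' @return An object of class `regression_fit` with fields `slope`,
#'   `intercept`, `r`, `r_squared`, `p_value`, `stderr_estimate` (residual
#'   standard error), and `ci_band` (data.frame `x`, `fit`, `lower`,
#'   `upper` at the observed x, sorted).
#' @export
fit_volume_regression <- function(x, y, conf_level = 0.95) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0) stop("predictor is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  xs <- sort(unique(x))
  band <- stats::predict(fit, newdata = data.frame(x = xs),
                         interval = "confidence", level = conf_level)
  r <- stats::cor(x, y)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = r, r_squared = r^2,
                 p_value = unname(sm$coefficients[2, 4]),
                 stderr_estimate = sm$sigma,
                 ci_band = data.frame(x = xs, fit = band[, "fit"],
                                      lower = band[, "lwr"],
                                      upper = band[, "upr"]),
                 n = length(x)),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(
    "regression_fit: y = %.4f x + %.4f; R = %.4f (R^2 = %.4f), p = %.3g, s = %.4f, n = %d\n",
    x$slope, x$intercept, x$r, x$r_squared, x$p_value, x$stderr_estimate,
    x$n))
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over the standard formulation returning `(W, p)`; rejects
#' degenerate samples explicitly.
#'
#' @param x numeric sample, `3 <= n <= 5000`, not constant.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3) stop("Shapiro-Wilk needs n >= 3", call. = FALSE)
  if (stats::sd(x) == 0) stop("sample is constant", call. = FALSE)
  ht <- stats::shapiro.test(x)
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Levene's test for homogeneity of variance (two groups)
#'
#' Brown-Forsythe form (absolute deviations from the group medians), the
#' default of the standard implementations. Returns the test statistic and
#' p-value.
#'
#' @param a,b numeric samples.
#' @return list with `W` (the F statistic of the deviations ANOVA) and
#'   `p`.
#' @export
levene <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3 || length(b) < 3)
    stop("Levene's test needs n >= 3 per group", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stop("both samples are constant", call. = FALSE)
  res <- car::leveneTest(c(a, b),
                         factor(rep(c("a", "b"), c(length(a), length(b)))))
  list(W = res[1, "F value"], p = res[1, "Pr(>F)"])
}

#' Two-tailed Wilcoxon signed-rank test for paired samples
#'
#' Differences of exactly zero are dropped (the classic treatment); tied
#' absolute differences receive midranks. For `n <= exact_limit` non-zero
#' differences the p-value comes from the exact permutation distribution
#' of the positive-rank sum over all 2^n equiprobable sign assignments
#' (computed by convolution, so ties are handled exactly); above that, the
#' normal approximation with tie-corrected variance and continuity
#' correction is used.
#'
#' @param a,b paired numeric samples of equal length.
#' @param exact_limit largest n for which the exact distribution is used.
#' @return Two-tailed p-value; attributes `statistic` (positive-rank sum
#'   V), `n_used`, `exact`.
#' @export
wilcoxon_signed_rank <- function(a, b, exact_limit = 25L) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[is.finite(d) & d != 0]
  n <- length(d)
  if (n < 1) stop("all paired differences are zero", call. = FALSE)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_limit) {
    p <- signed_rank_exact_p(r, v)
    exact <- TRUE
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    z <- v - mu
    z <- (z - sign(z) * 0.5) / sigma  # continuity correction
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  structure(p, statistic = v, n_used = n, exact = exact)
}

# Exact two-sided p for the positive-rank sum: P(|V - mu| >= |v - mu|)
# under random signs. Ranks may be midranks (k/2); work on doubled ranks
# so all sums are integers. The distribution of V is symmetric about mu,
# so the two-sided p equals P(V <= min(v, S - v)) + P(V >= max(v, S - v)).
signed_rank_exact_p <- function(ranks, v) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  counts <- numeric(total + 1)  # counts[w + 1] = #assignments with 2V = w
  counts[1] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), counts[seq_len(total + 1 - ri)])
    counts <- counts + shifted
  }
  counts <- counts / 2^length(r2)
  v2 <- as.integer(round(2 * v))
  lo <- min(v2, total - v2)
  hi <- max(v2, total - v2)
  p <- sum(counts[seq_len(lo + 1)]) + sum(counts[(hi + 1):(total + 1)])
  min(1, p)
}

#' Two-tailed paired t-test
#'
#' @param a,b paired numeric samples (n >= 3).
#' @return Two-tailed p-value; attribute `statistic` (t).
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  ht <- stats::t.test(a, b, paired = TRUE)
  structure(ht$p.value, statistic = unname(ht$statistic))
}

#' Paired-sample Cohen's d
#'
#' Mean of the paired differences divided by their standard deviation
#' (the paired-sample form, not a pooled-SD form). Conventional
#' qualitative cuts: |d| >= 0.8 large, >= 0.5 medium, >= 0.2 small,
#' otherwise negligible.
#'
#' @param a,b paired numeric samples.
#' @return d; attribute `magnitude` holds the qualitative label.
#' @export
cohens_d_paired <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  s <- stats::sd(d)
  if (s == 0) stop("paired differences have zero SD", call. = FALSE)
  val <- mean(d) / s
  mag <- if (abs(val) >= 0.8) "large" else if (abs(val) >= 0.5) "medium"
  else if (abs(val) >= 0.2) "small" else "negligible"
  structure(val, magnitude = mag)
}

#' Holm-Bonferroni step-down correction
#'
#' Sorts the m p-values ascending; the i-th smallest is compared against
#' `alpha / (m - i + 1)`, and rejection stops at the first failure. With
#' two hypotheses at alpha = 0.05 the smaller p-value faces an adjusted
#' threshold of 0.025 and, if it rejects, the larger faces 0.05.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param alpha family-wise significance level.
#' @return data.frame in the input order with `p`, `rank`, `threshold`,
#'   `reject`.
#' @export
holm_bonferroni <- function(p, alpha = 0.05) {
  stopifnot(all(is.finite(p)), all(p >= 0 & p <= 1), alpha > 0)
  m <- length(p)
  ord <- order(p)
  thresh_sorted <- alpha / (m - seq_len(m) + 1)
  reject_sorted <- logical(m)
  for (i in seq_len(m)) {
    if (p[ord[i]] <= thresh_sorted[i]) reject_sorted[i] <- TRUE
    else break
  }
  out <- data.frame(p = p, rank = NA_integer_, threshold = NA_real_,
                    reject = NA)
  out$rank[ord] <- seq_len(m)
  out$threshold[ord] <- thresh_sorted
  out$reject[ord] <- reject_sorted
  out
}

#' Paired comparison of overlap metrics between two mask families
#'
#' Implements the gated testing workflow for the two primary hypotheses
#' (a modality effect on Dice, and on Hausdorff distance): each group is
#' checked for normality with Shapiro-Wilk (alpha 0.05) and the pair for
#' homogeneity of variance with Levene's test; when both groups pass
#' Shapiro and Levene passes, the two-tailed paired t-test is used,
#' otherwise the two-tailed Wilcoxon signed-rank test. Practical
#' importance is quantified with the paired-sample Cohen's d, and the two
#' test p-values are controlled with Holm-Bonferroni at the family-wise
#' alpha.
#'
#' @param dsc_a,dsc_b paired Dice samples for the two mask families
#'   (paired by patient and pre/post pair).
#' @param hd_a,hd_b paired Hausdorff samples, same pairing.
#' @param alpha family-wise significance level.
#' @param gate_alpha alpha of the Shapiro/Levene gates.
#' @return List of two `paired_comparison` objects (`dsc`, `hd`), each
#'   with the gate results, chosen test, p-value, Cohen's d, Holm
#'   threshold and significance flag.
#' @export
compare_modalities <- function(dsc_a, dsc_b, hd_a, hd_b, alpha = 0.05,
                               gate_alpha = 0.05) {
  if (length(dsc_a) != length(dsc_b) || length(hd_a) != length(hd_b))
    stop("samples must be paired (equal lengths within each hypothesis)",
         call. = FALSE)
  one <- function(label, a, b) {
    ok <- is.finite(a) & is.finite(b)
    a <- a[ok]; b <- b[ok]
    sh_a <- shapiro_wilk(a)
    sh_b <- shapiro_wilk(b)
    lv <- levene(a, b)
    normal <- sh_a$p > gate_alpha && sh_b$p > gate_alpha
    homosced <- lv$p > gate_alpha
    chosen <- if (normal && homosced) "PAIRED_T" else "WILCOXON"
    if (all(a == b)) {
      # degenerate: the paired groups are identical; no evidence of any
      # difference, and neither test statistic is defined
      pv <- structure(1, statistic = NA_real_)
      d <- structure(0, magnitude = "negligible")
    } else {
      pv <- if (chosen == "PAIRED_T") paired_t(a, b)
            else wilcoxon_signed_rank(a, b)
      d <- cohens_d_paired(a, b)
    }
    list(hypothesis = label, n = length(a),
         shapiro_a = sh_a, shapiro_b = sh_b, levene = lv,
         chosen_test = chosen, test_p = as.numeric(pv),
         test_statistic = attr(pv, "statistic"),
         cohens_d = as.numeric(d),
         d_magnitude = attr(d, "magnitude"))
  }
  cmp_dsc <- one("DSC", dsc_a, dsc_b)
  cmp_hd <- one("HD", hd_a, hd_b)
  holm <- holm_bonferroni(c(cmp_dsc$test_p, cmp_hd$test_p), alpha)
  cmp_dsc$holm_threshold <- holm$threshold[1]
  cmp_dsc$significant <- holm$reject[1]
  cmp_hd$holm_threshold <- holm$threshold[2]
  cmp_hd$significant <- holm$reject[2]
  class(cmp_dsc) <- class(cmp_hd) <- "paired_comparison"
  list(dsc = cmp_dsc, hd = cmp_hd)
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf(
    paste0("paired_comparison [%s] n=%d: Shapiro W=%.3f p=%.3f / W=%.3f ",
           "p=%.3f; Levene W=%.3f p=%.3f -> %s p=%.4f; d=%.2f (%s); ",
           "Holm threshold %.4f -> %s\n"),
    x$hypothesis, x$n, x$shapiro_a$W, x$shapiro_a$p, x$shapiro_b$W,
    x$shapiro_b$p, x$levene$W, x$levene$p, x$chosen_test, x$test_p,
    x$cohens_d, x$d_magnitude, x$holm_threshold,
    if (isTRUE(x$significant)) "significant" else "not significant"))
  invisible(x)
}
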