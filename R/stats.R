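#' Dice similarity coefficient
#'
#' Spatial overlap of two binary masks: `2 |A & B| / (|A| + |B|)`.
#'
#' @param a,b Logical (or 0/1) arrays of identical dimensions.
#' @return Scalar in [0, 1].
#' @examples
#' m <- array(FALSE, c(4, 4, 4)); m[1:2, , ] <- TRUE
#' dice(m, m)
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("masks must share the same grid")
  a <- a != 0; b <- b != 0
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) stop("Dice coefficient undefined: both masks empty")
  2 * sum(a & b) / (na + nb)
}

#' Paired mean absolute percentage error
#'
#' Repeatability MAPE between two measurement series on the same
#' subjects (e.g. supine and prone scans), with the pair mean as the
#' denominator: `100 / N * sum(|x_s - x_p| / ((x_s + x_p) / 2))`.
#'
#' @param x_s,x_p Numeric vectors of equal length (N >= 1).
#' @return Percent.
#' @examples
#' mape_paired(110, 90)  # 20
#' @export
mape_paired <- function(x_s, x_p) {
  if (length(x_s) != length(x_p) || length(x_s) < 1)
    stop("need equal-length non-empty series")
  m <- (x_s + x_p) / 2
  if (any(m == 0)) stop("pair mean of zero")
  100 * mean(abs(x_s - x_p) / m)
}

#' Truth-referenced mean absolute percentage error
#'
#' Accuracy MAPE of measurements against known true values:
#' `100 / N * sum(|x_m - x_actual| / x_actual)`.
#'
#' @param x_m Measured values.
#' @param x_actual True values (non-zero), same length.
#' @return Percent.
#' @examples
#' mape_truth(c(120, 90), c(100, 100))  # 15
#' @export
mape_truth <- function(x_m, x_actual) {
  if (length(x_m) != length(x_actual) || length(x_m) < 1)
    stop("need equal-length non-empty series")
  if (any(x_actual == 0)) stop("zero true value")
  100 * mean(abs(x_m - x_actual) / abs(x_actual))
}

#' Coefficient of repeatability
#'
#' 2.77 times the within-subject standard deviation of paired
#' measurements; for pairs the within-subject SD is
#' `s_w = sqrt(sum(d_i^2) / (2 N))` with `d_i = x_s - x_p`.  The 95%
#' confidence interval uses the chi-square distribution of
#' `sum(d_i^2) / (2 s_w^2)` on N degrees of freedom.
#'
#' @param x_s,x_p Numeric vectors, N >= 2 pairs.
#' @param conf_level Confidence level for the interval.
#' @return Tibble with `s_w`, `cr`, `cr_lo`, `cr_hi`, `n`.
#' @examples
#' coefficient_of_repeatability(c(20, 30, 40, 50), c(10, 20, 30, 40))
#' @export
coefficient_of_repeatability <- function(x_s, x_p, conf_level = 0.95) {
  if (length(x_s) != length(x_p) || length(x_s) < 2)
    stop("need at least 2 pairs")
  d <- x_s - x_p
  n <- length(d)
  s_w <- sqrt(sum(d^2) / (2 * n))
  a <- (1 - conf_level) / 2
  lo <- s_w * sqrt(n / stats::qchisq(1 - a, df = n))
  hi <- s_w * sqrt(n / stats::qchisq(a, df = n))
  tibble::tibble(s_w = s_w, cr = 2.77 * s_w,
                 cr_lo = 2.77 * lo, cr_hi = 2.77 * hi, n = n)
}

#' Bland-Altman agreement analysis
#'
#' Differences of paired measurements against their pair means, with
#' the mean difference, 95% limits of agreement (mean +/- 1.96 SD) and
#' t-based 95% confidence intervals of the mean and of each limit.  In
#' percent mode the differences are expressed as a percentage of the
#' pair mean (percentage volume difference).
#'
#' @param x_s,x_p Numeric vectors, N >= 3 pairs.
#' @param percent Report differences as percent of the pair mean?
#' @return A `bland_altman` object; see [tidy.bland_altman()] and
#'   [glance.bland_altman()].
#' @export
bland_altman <- function(x_s, x_p, percent = FALSE) {
  if (length(x_s) != length(x_p) || length(x_s) < 3)
    stop("need at least 3 pairs")
  m <- (x_s + x_p) / 2
  d <- x_s - x_p
  if (percent) {
    if (any(m == 0)) stop("pair mean of zero in percent mode")
    d <- 100 * d / m
  }
  n <- length(d)
  md <- mean(d); sd_d <- stats::sd(d)
  tcrit <- stats::qt(0.975, n - 1)
  se_mean <- sd_d / sqrt(n)
  se_loa <- sd_d * sqrt(1 / n + 1.96^2 / (2 * (n - 1)))
  structure(list(
    data = tibble::tibble(mean = m, diff = d),
    percent = percent,
    mean_diff = md,
    mean_diff_ci = md + c(-1, 1) * tcrit * se_mean,
    sd_diff = sd_d,
    loa_lower = md - 1.96 * sd_d,
    loa_upper = md + 1.96 * sd_d,
    loa_lower_ci = md - 1.96 * sd_d + c(-1, 1) * tcrit * se_loa,
    loa_upper_ci = md + 1.96 * sd_d + c(-1, 1) * tcrit * se_loa,
    n = n), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  u <- if (x$percent) "%" else ""
  cat(sprintf("<bland_altman> n = %d pairs%s\n", x$n,
              if (x$percent) " (percent differences)" else ""))
  cat(sprintf("  mean difference %.3g%s (95%% CI %.3g to %.3g)\n",
              x$mean_diff, u, x$mean_diff_ci[1], x$mean_diff_ci[2]))
  cat(sprintf("  limits of agreement %.3g%s to %.3g%s\n",
              x$loa_lower, u, x$loa_upper, u))
  invisible(x)
}

#' Tidy a Bland-Altman object
#' @param x A `bland_altman`.
#' @param ... Unused.
#' @return Per-pair tibble of pair means and differences.
#' @export
tidy.bland_altman <- function(x, ...) x$data

#' One-row summary of a Bland-Altman object
#' @param x A `bland_altman`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(mean_diff = x$mean_diff, sd_diff = x$sd_diff,
                 loa_lower = x$loa_lower, loa_upper = x$loa_upper,
                 mean_diff_lo = x$mean_diff_ci[1],
                 mean_diff_hi = x$mean_diff_ci[2], n = x$n)
}

#' Linear regression and Pearson correlation summary
#'
#' Ordinary least-squares trend line with t-based 95% confidence
#' intervals of the slope, plus the Pearson correlation coefficient
#' with its Fisher-z interval and two-sided p value.  Standard model
#' fits via [stats::lm()] and [stats::cor.test()].
#'
#' @param x,y Numeric vectors (N >= 3, x non-constant).
#' @return One-row tibble: slope, intercept, slope CI, r, r CI, p.
#' @export
regression_and_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("x is constant; regression undefined")
  fit <- stats::lm(y ~ x)
  ci <- stats::confint(fit)
  ct <- stats::cor.test(x, y)
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    slope_lo = ci[2, 1], slope_hi = ci[2, 2],
    intercept = unname(stats::coef(fit)[1]),
    r = unname(ct$estimate),
    r_lo = if (!is.null(ct$conf.int)) ct$conf.int[1] else NA_real_,
    r_hi = if (!is.null(ct$conf.int)) ct$conf.int[2] else NA_real_,
    p_value = ct$p.value, n = length(x))
}

#' ROC analysis of a continuous score
#'
#' Area under the ROC curve by the Mann-Whitney construction (each
#' positive-negative pair contributes 1 when the positive scores
#' higher, 1/2 on ties), with the Hanley-McNeil standard error for the
#' confidence interval.  At the supplied decision threshold (score >=
#' threshold calls positive) -- or at the Youden-optimal threshold when
#' none is given -- sensitivity, specificity and accuracy are reported.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels Binary labels (logical or 0/1); both classes required.
#' @param threshold Optional decision threshold.
#' @param conf_level Confidence level.
#' @return An `rv_roc` object; `tidy()` gives the curve points,
#'   `glance()` the AUC, CI, threshold, sensitivity, specificity and
#'   accuracy.
#' @examples
#' roc_analysis(c(3, 4, 5, 1, 2, 3), c(1, 1, 1, 0, 0, 0))
#' @export
roc_analysis <- function(scores, labels, threshold = NULL,
                         conf_level = 0.95) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (!any(labels) || all(labels))
    stop("both classes must be present")
  pos <- scores[labels]; neg <- scores[!labels]
  n1 <- length(pos); n0 <- length(neg)
  # Mann-Whitney: mean over all pairs of win + half-tie
  cmp <- outer(pos, neg, "-")
  auc <- (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (n1 * n0)
  # Hanley-McNeil SE
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(auc + c(-1, 1) * z * se, 0), 1)

  thr_grid <- c(-Inf, sort(unique(scores)), Inf)
  curve <- tibble::tibble(
    threshold = thr_grid,
    tpr = vapply(thr_grid, function(t) mean(pos >= t), numeric(1)),
    fpr = vapply(thr_grid, function(t) mean(neg >= t), numeric(1)))
  if (is.null(threshold)) {
    youden <- curve$tpr - curve$fpr
    threshold <- curve$threshold[which.max(youden)]
  }
  pred <- scores >= threshold
  sens <- mean(pred[labels]); spec <- mean(!pred[!labels])
  acc <- mean(pred == labels)
  structure(list(curve = curve, auc = auc, auc_ci = ci,
                 threshold = threshold,
                 sensitivity = 100 * sens, specificity = 100 * spec,
                 accuracy = 100 * acc, n_pos = n1, n_neg = n0),
            class = "rv_roc")
}

#' @export
print.rv_roc <- function(x, ...) {
  cat(sprintf("<rv_roc> AUC %.3f (95%% CI %.3f-%.3f), %d pos / %d neg\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$n_pos, x$n_neg))
  cat(sprintf(
    "  threshold %.3g: sensitivity %.1f, specificity %.1f, accuracy %.1f\n",
    x$threshold, x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' @export
tidy.rv_roc <- function(x, ...) x$curve

#' @export
glance.rv_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, auc_lo = x$auc_ci[1], auc_hi = x$auc_ci[2],
                 threshold = x$threshold, sensitivity = x$sensitivity,
                 specificity = x$specificity, accuracy = x$accuracy)
}

#' Nonparametric group comparisons (call-through utilities)
#'
#' Thin wrappers over the standard Mann-Whitney / Wilcoxon rank-sum and
#' Kruskal-Wallis tests for comparing uptake ratios between patient
#' subgroups; provided for completeness of the evaluation workflow, the
#' implementations are [stats::wilcox.test()] and
#' [stats::kruskal.test()].
#'
#' @param x Numeric response.
#' @param g Group factor (two levels for `group_test_wilcox`).
#' @return Tidy one-row tibble with the statistic and p value.
#' @export
group_test_wilcox <- function(x, g) {
  g <- factor(g)
  if (nlevels(g) != 2) stop("need exactly two groups")
  w <- stats::wilcox.test(x ~ g)
  tibble::tibble(statistic = unname(w$statistic), p_value = w$p.value,
                 method = "Mann-Whitney")
}

#' @rdname group_test_wilcox
#' @export
group_test_kruskal <- function(x, g) {
  k <- stats::kruskal.test(x, factor(g))
  tibble::tibble(statistic = unname(k$statistic), p_value = k$p.value,
                 method = "Kruskal-Wallis")
}
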