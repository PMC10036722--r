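test_that("Dice coefficient covers the worked cases and degeneracies", {
  m <- array(FALSE, c(6, 6, 6))
  a <- m; a[1:2, , ] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- m; b[5:6, , ] <- TRUE
  expect_equal(dice(a, b), 0)
  # |A| = |B| = 100, overlap 50
  a2 <- rep(c(TRUE, FALSE), c(100, 100))
  b2 <- rep(c(FALSE, TRUE, FALSE), c(50, 100, 50))
  dim(a2) <- dim(b2) <- c(10, 10, 2)
  expect_equal(dice(a2, b2), 0.5)
  expect_error(dice(m, m), "empty")
  expect_error(dice(a, array(FALSE, c(5, 5, 5))), "grid")
})

test_that("paired MAPE uses the pair-mean denominator", {
  expect_equal(mape_paired(c(5, 9), c(5, 9)), 0)
  expect_equal(mape_paired(110, 90), 20)
  expect_equal(mape_paired(c(110, 100), c(90, 100)), 10)
  # symmetric under swapping the two series
  set.seed(1)
  x <- runif(10, 50, 200); y <- runif(10, 50, 200)
  expect_equal(mape_paired(x, y), mape_paired(y, x))
  expect_error(mape_paired(1, -1), "zero")
})

test_that("truth-referenced MAPE uses the truth denominator", {
  expect_equal(mape_truth(c(7, 7), c(7, 7)), 0)
  expect_equal(mape_truth(120, 100), 20)
  expect_equal(mape_truth(c(120, 90), c(100, 100)), 15)
  # not symmetric, unlike the paired form
  expect_false(isTRUE(all.equal(mape_truth(120, 100),
                                mape_truth(100, 120))))
  expect_error(mape_truth(5, 0), "zero")
})

test_that("coefficient of repeatability matches the closed form", {
  expect_equal(coefficient_of_repeatability(c(4, 4, 4), c(4, 4, 4))$cr, 0)
  r <- coefficient_of_repeatability(c(20, 30, 40, 50), c(10, 20, 30, 40))
  expect_close(r$s_w, 10 / sqrt(2), 1e-9)
  expect_close(r$cr, 19.59, 0.005)
  expect_true(r$cr_lo < r$cr && r$cr < r$cr_hi)
  # scale equivariance
  r2 <- coefficient_of_repeatability(2 * c(20, 30, 40, 50),
                                     2 * c(10, 20, 30, 40))
  expect_equal(r2$cr, 2 * r$cr)
  expect_error(coefficient_of_repeatability(1, 2), "at least 2")
})

test_that("Bland-Altman summaries and invariances", {
  b0 <- bland_altman(c(5, 6, 7), c(5, 6, 7))
  expect_equal(b0$mean_diff, 0)
  expect_equal(b0$loa_lower, 0)
  expect_equal(b0$loa_upper, 0)

  # percent differences +10, -10, +10, -10: mean 0, SD 11.547
  x <- c(105, 95, 105, 95); y <- c(95, 105, 95, 105)
  bp <- bland_altman(x, y, percent = TRUE)
  expect_close(bp$mean_diff, 0, 1e-9)
  expect_close(bp$sd_diff, sd(c(10, -10, 10, -10)), 1e-9)
  expect_close(bp$loa_upper, 1.96 * 11.54701, 0.001)

  # absolute differences unchanged by a common shift
  b1 <- bland_altman(c(10, 20, 35), c(12, 18, 30))
  b2 <- bland_altman(c(10, 20, 35) + 100, c(12, 18, 30) + 100)
  expect_equal(b1$mean_diff, b2$mean_diff)
  expect_equal(b1$sd_diff, b2$sd_diff)

  expect_error(bland_altman(1:2, 2:3), "at least 3")
  g <- glance(bp)
  expect_equal(g$n, 4)
  expect_s3_class(tidy(bp), "tbl_df")
})

test_that("regression and correlation match a hand-computed oracle", {
  x <- c(1, 2, 3); y <- c(1, 2, 3)
  r <- regression_and_correlation(x, y)
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_equal(r$r, 1, tolerance = 1e-12)

  set.seed(10)
  x <- runif(10, 40, 220)
  y <- 2 * x + rnorm(10, sd = 5)
  r2 <- regression_and_correlation(x, y)
  # closed-form least squares
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  ic <- mean(y) - sl * mean(x)
  rr <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_close(r2$slope, sl, 1e-10)
  expect_close(r2$intercept, ic, 1e-10)
  expect_close(r2$r, rr, 1e-10)
  expect_true(r2$slope_lo < sl & sl < r2$slope_hi)
  expect_error(regression_and_correlation(c(1, 1, 1), c(1, 2, 3)),
               "constant")
})

test_that("ROC analysis follows the Mann-Whitney construction", {
  # positives {3,4,5}, negatives {1,2,3}: 8 wins + half a tie over 9 pairs
  r <- roc_analysis(c(3, 4, 5, 1, 2, 3), c(1, 1, 1, 0, 0, 0))
  expect_close(r$auc, 8.5 / 9, 1e-12)

  perfect <- roc_analysis(c(10, 11, 12, 1, 2), c(1, 1, 1, 0, 0))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)

  set.seed(2)
  big <- roc_analysis(rnorm(2000), rep(c(0, 1), 1000))
  expect_close(big$auc, 0.5, 0.05)

  expect_error(roc_analysis(1:5, rep(1, 5)), "both classes")
})

test_that("Mann-Whitney AUC equals trapezoidal ROC integration", {
  trapz_auc <- function(scores, labels) {
    r <- roc_analysis(scores, labels)
    cur <- r$curve[order(r$curve$fpr, r$curve$tpr), ]
    sum(diff(cur$fpr) * (head(cur$tpr, -1) + tail(cur$tpr, -1)) / 2)
  }
  set.seed(33)
  for (i in 1:5) {
    n <- sample(10:40, 1)
    scores <- round(rnorm(n), 1)          # rounding forces ties
    labels <- rbinom(n, 1, 0.5)
    if (!any(labels) || all(labels)) next
    expect_close(roc_analysis(scores, labels)$auc,
                 trapz_auc(scores, labels), 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, plogis(scores))
  if (any(labels) && !all(labels)) {
    ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores,
                                                quiet = TRUE)))
    expect_close(roc_analysis(scores, labels)$auc, as.numeric(ref), 1e-10)
  }
})

test_that("repeatability CR and Bland-Altman limits agree when unbiased", {
  set.seed(8)
  x <- runif(200, 50, 200)
  y <- x + rnorm(200, sd = 6)
  cr <- coefficient_of_repeatability(x, y)$cr
  ba <- bland_altman(x, y)
  half_loa <- (ba$loa_upper - ba$loa_lower) / 2
  # CR = 2.77 s_w vs LoA half-width 1.96 sd(d); with mean(d) ~ 0,
  # sd(d) ~ sqrt(2) s_w so the ratio is 2.77 / 2.77 ~ 1
  expect_close(cr / half_loa, 1, 0.05)
})

test_that("group-test wrappers return tidy rows", {
  set.seed(4)
  x <- c(rnorm(10), rnorm(10, 2))
  g <- rep(c("a", "b"), each = 10)
  w <- group_test_wilcox(x, g)
  expect_true(w$p_value < 0.05)
  k <- group_test_kruskal(x, g)
  expect_s3_class(k, "tbl_df")
  expect_error(group_test_wilcox(x, rep("a", 20)), "two groups")
})
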