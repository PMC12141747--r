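test_that("ROC handles the textbook fixtures exactly", {
  r <- roc_curve(c(1, 2, 3, 10, 11, 12), rep(c(FALSE, TRUE), each = 3),
                 n_boot = 0)
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  # positives {2, 4}, negatives {1, 3}: 3 concordant of 4 pairs
  r2 <- roc_curve(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, TRUE), n_boot = 0)
  expect_equal(r2$auc, 0.75)
  expect_error(roc_curve(1:4, rep(TRUE, 4), n_boot = 0), "both classes")
})

test_that("rank AUC equals the brute-force pairwise oracle", {
  withr::with_seed(31, {
    for (i in 1:25) {
      n <- sample(10:100, 1)
      scores <- round(rnorm(n), sample(0:2, 1))  # induce ties
      labels <- runif(n) < 0.5
      if (!any(labels) || all(labels)) next
      expect_equal(roc_curve(scores, labels, n_boot = 0)$auc,
                   oracle_auc(scores, labels), tolerance = 1e-12)
    }
  })
})

test_that("AUC equals the trapezoidal area of the ROC curve", {
  withr::with_seed(32, {
    scores <- round(rnorm(60), 1)
    labels <- runif(60) < 0.4
  })
  r <- roc_curve(scores, labels, n_boot = 0)
  ord <- order(r$fpr, r$tpr)
  trap <- sum(diff(r$fpr[ord]) *
                (head(r$tpr[ord], -1) + tail(r$tpr[ord], -1)) / 2)
  expect_equal(r$auc, trap, tolerance = 1e-12)
})

test_that("AUC is invariant to monotone transforms and flips with sign", {
  withr::with_seed(33, {
    scores <- rnorm(50)
    labels <- runif(50) < 0.5
  })
  a <- roc_curve(scores, labels, n_boot = 0)$auc
  expect_equal(roc_curve(exp(scores), labels, n_boot = 0)$auc, a,
               tolerance = 1e-12)
  expect_equal(roc_curve(-scores, labels, n_boot = 0)$auc, 1 - a,
               tolerance = 1e-12)
})

test_that("rank AUC agrees with an independent ROC implementation", {
  withr::with_seed(34, {
    scores <- round(rnorm(80), 1)
    labels <- runif(80) < 0.5
  })
  ours <- roc_curve(scores, labels, n_boot = 0)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = labels,
                                        predictor = scores,
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("label permutation drives the mean AUC to one half", {
  pn <- auc_permutation_null(n = 52, n_perm = 1000, seed = 3)
  expect_lt(abs(pn$mean_auc - 0.5), 0.02)
})

test_that("bootstrap intervals are seeded and ordered", {
  withr::with_seed(35, {
    scores <- c(rnorm(25), rnorm(25, 1.2))
    labels <- rep(c(FALSE, TRUE), each = 25)
  })
  r1 <- roc_curve(scores, labels, n_boot = 300, seed = 7)
  r2 <- roc_curve(scores, labels, n_boot = 300, seed = 7)
  expect_identical(r1$auc_ci, r2$auc_ci)
  expect_true(r1$auc_ci[1] <= r1$auc && r1$auc <= r1$auc_ci[2])
})

test_that("a pure-noise second predictor does not degrade the combination", {
  withr::with_seed(36, {
    diffs <- replicate(300, {
      labels <- rep(c(FALSE, TRUE), each = 26)
      strong <- rnorm(52) + 1.5 * labels
      noise <- rnorm(52)
      comb <- combine_predictors(data.frame(strong, noise), labels,
                                 n_boot = 0)
      comb$roc$auc - thetapac:::rank_auc(strong, labels)
    })
  })
  expect_gt(mean(diffs), -0.02)
})

test_that("duplicated predictors are reported as rank-deficient", {
  withr::with_seed(37, {
    x <- rnorm(40)
    labels <- runif(40) < 0.5
  })
  expect_warning(
    res <- combine_predictors(data.frame(a = x, b = x), labels, n_boot = 0),
    "rank-deficient")
  expect_true(length(res$rank_deficient) >= 1)
})

test_that("perfect separation triggers the flagged penalized fallback", {
  labels <- rep(c(FALSE, TRUE), each = 10)
  x <- c(rnorm(10, -3, 0.1), rnorm(10, 3, 0.1))
  res <- combine_predictors(data.frame(x = x), labels, n_boot = 0)
  expect_true(res$separation)
  expect_true(all(is.finite(res$coefficients)))
  expect_equal(res$roc$auc, 1)
})

test_that("per-predictor likelihood-ratio chi-squares match glm deviances", {
  withr::with_seed(38, {
    labels <- rep(c(FALSE, TRUE), each = 30)
    a <- rnorm(60) + 1.2 * labels
    b <- rnorm(60) + 0.4 * labels
  })
  res <- combine_predictors(data.frame(a, b), labels, n_boot = 0)
  full <- glm(labels ~ scale(a) + scale(b), family = binomial())
  red <- glm(labels ~ scale(b), family = binomial())
  expect_equal(res$predictor_chi2$chi2[res$predictor_chi2$predictor == "a"],
               red$deviance - full$deviance, tolerance = 1e-8)
  expect_gt(res$predictor_chi2$chi2[1],
            res$predictor_chi2$chi2[2])
})
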