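test_that("ROC curves have the documented shape and endpoints", {
  scores <- c(0.9, 0.8, 0.4, 0.3)
  labels <- c(1, 1, 0, 0)
  curve <- roc_curve(scores, labels)
  expect_equal(curve$fpr[1], 0)
  expect_equal(curve$tpr[1], 0)
  expect_equal(curve$fpr[nrow(curve)], 1)
  expect_equal(curve$tpr[nrow(curve)], 1)
  expect_true(all(diff(curve$fpr) >= 0))
  expect_true(all(diff(curve$tpr) >= 0))
  # perfect separation passes through (0, 1)
  expect_true(any(curve$fpr == 0 & curve$tpr == 1))
})

test_that("tied scores collapse to the no-discrimination diagonal", {
  curve <- roc_curve(rep(0.5, 10), c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(nrow(curve), 2L)
  expect_equal(auc(curve), 0.5)
})

test_that("lower_is_positive equals higher_is_positive on negated scores", {
  set.seed(12)
  s <- round(rnorm(40), 1) # include ties
  y <- rbinom(40, 1, 0.4)
  lo <- roc_curve(s, y, "lower_is_positive")
  hi <- roc_curve(-s, y, "higher_is_positive")
  expect_equal(lo$fpr, hi$fpr)
  expect_equal(lo$tpr, hi$tpr)
  expect_equal(auc(lo), auc(hi))
})

test_that("single-class labels are rejected", {
  expect_error(roc_curve(runif(5), rep(1, 5)), "single-class")
})

test_that("the trapezoidal area counts correctly ordered pairs", {
  # positives {0.9, 0.4}, negatives {0.5, 0.1}: 3 of 4 pairs ordered
  expect_equal(
    auc(roc_curve(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0))), 0.75
  )
  expect_equal(
    auc(roc_curve(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))), 1.0
  )
})

test_that("trapezoidal AUC equals the exhaustive pair-count oracle", {
  set.seed(22)
  for (i in 1:20) {
    n_pos <- sample(2:50, 1)
    n_neg <- sample(2:50, 1)
    scores <- c(
      round(rnorm(n_pos, 1), 1), round(rnorm(n_neg), 1) # rounding makes ties
    )
    labels <- rep(c(1, 0), c(n_pos, n_neg))
    expect_equal(
      auc(roc_curve(scores, labels)),
      oracle_auc(scores, labels),
      tolerance = 1e-12
    )
  }
})

test_that("AUC respects score symmetry and monotone transforms", {
  set.seed(32)
  s <- rnorm(60) # continuous: ties almost surely absent
  y <- rbinom(60, 1, 0.5)
  expect_equal(
    auc(roc_curve(s, y)) + auc(roc_curve(-s, y)), 1,
    tolerance = 1e-12
  )
  expect_equal(
    auc(roc_curve(s, y)), auc(roc_curve(exp(s), y)),
    tolerance = 1e-12
  )
})

test_that("AUC matches an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(42)
  s <- rnorm(100)
  y <- rbinom(100, 1, 0.3)
  expect_equal(
    auc(roc_curve(s, y)),
    as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<"))),
    tolerance = 1e-12
  )
})

test_that("the Hanley-McNeil closed form reproduces known quantities", {
  hm <- auc_se(0.5, 1, 1)
  expect_equal(hm$q1, 1 / 3)
  expect_equal(hm$q2, 1 / 3)
  expect_equal(hm$se, 0.5)

  expect_equal(auc_se(1, 25, 100)$se, 0)
  expect_equal(auc_se(0, 25, 100)$se, 0)

  for (theta in seq(0.05, 0.95, by = 0.15)) {
    for (n_a in c(1, 5, 50)) {
      for (n_n in c(1, 20, 200)) {
        got <- auc_se(theta, n_a, n_n)
        want <- oracle_hanley_se(theta, n_a, n_n)
        expect_equal(got$q1, want$q1, tolerance = 1e-12)
        expect_equal(got$q2, want$q2, tolerance = 1e-12)
        expect_equal(got$se, want$se, tolerance = 1e-12)
      }
    }
  }
  expect_error(auc_se(1.2, 5, 5), "\\[0, 1\\]")
})

test_that("correlated AUC comparison computes the documented statistic", {
  est <- function(omega, se) {
    structure(list(omega = omega, se = se), class = "auc_estimate")
  }
  # identical estimates: z = 0 for any r
  same <- compare_auc(est(0.8, 0.05), est(0.8, 0.05), r = 0.3)
  expect_equal(same$z, 0)
  expect_equal(same$p_two_sided, 1)

  # independence: se_diff is the root sum of squares
  ind <- compare_auc(est(0.8, 0.03), est(0.7, 0.04), r = 0)
  expect_equal(ind$se_diff, sqrt(0.03^2 + 0.04^2))

  # worked case: se 0.1 each, r 0.5, difference 0.05
  cmp <- compare_auc(est(0.80, 0.1), est(0.75, 0.1), r = 0.5)
  expect_equal(cmp$se_diff, 0.1)
  expect_equal(cmp$z, 0.5)
  expect_equal(cmp$p_two_sided, 2 * pnorm(-0.5))

  expect_error(compare_auc(est(0.9, 0), est(0.7, 0), r = 0), "zero standard")
  expect_equal(compare_auc(est(0.9, 0), est(0.9, 0), r = 0)$z, 0)
  expect_error(compare_auc(est(0.8, 0.1), est(0.7, 0.1), r = 2), "\\[-1, 1\\]")
})

test_that("both r estimators behave at the identity and under independence", {
  set.seed(52)
  y <- rep(c(1, 0), c(100, 100))
  s <- rnorm(200)
  expect_equal(estimate_r(s, s, y, "average"), 1)
  expect_equal(estimate_r(s, s, y, "delong"), 1)

  y2 <- rep(c(1, 0), c(2000, 2000))
  a <- rnorm(4000)
  b <- rnorm(4000)
  expect_lt(abs(estimate_r(a, b, y2, "average")), 0.1)
  expect_lt(abs(estimate_r(a, b, y2, "delong")), 0.1)

  expect_error(estimate_r(s[1:4], s[1:4], c(1, 1, 0, 0)), "at least 3")
})

test_that("the two r estimators agree in sign on correlated scores", {
  set.seed(62)
  agree <- replicate(20, {
    y <- rep(c(1, 0), c(50, 150))
    base <- rnorm(200) + y
    a <- base + rnorm(200, sd = 0.7)
    b <- base + rnorm(200, sd = 0.7)
    sign(estimate_r(a, b, y, "average")) ==
      sign(estimate_r(a, b, y, "delong"))
  })
  expect_true(all(agree))
})

test_that("cross-validation partitions rows into near-equal folds", {
  ft <- tiny_feature_table(103, seed = 72)
  cv <- kfold_cv(ft, K = 10, seed = 5)
  expect_equal(sum(cv$fold_sizes), nrow(ft))
  expect_lte(diff(range(cv$fold_sizes)), 1L)
  expect_equal(cv$K, 10L)
})

test_that("cross-validation is bit-reproducible under a fixed seed", {
  ft <- tiny_feature_table(150, seed = 82)
  a <- kfold_cv(ft, K = 5, seed = 9)
  b <- kfold_cv(ft, K = 5, seed = 9)
  expect_identical(a, b)
  # leave-one-out has a unique partition: the seed cannot matter
  small <- tiny_feature_table(30, seed = 83)
  expect_equal(
    kfold_cv(small, K = 30, seed = 1)$mean_prediction_error,
    kfold_cv(small, K = 30, seed = 2)$mean_prediction_error
  )
})

test_that("a pre-separated predictor drives the CV error to zero", {
  ft <- tiny_feature_table(200, seed = 92)
  ft$x_targetscan <- as.numeric(ft$label)
  cv <- suppressWarnings(
    kfold_cv(ft, feature_subset = "x_targetscan", K = 5, seed = 3)
  )
  expect_lt(cv$mean_prediction_error, 1e-4)
})

test_that("cross-validation guards its preconditions", {
  ft <- tiny_feature_table(50, seed = 93)
  expect_error(kfold_cv(ft, K = 1), "at least 2")
  expect_error(kfold_cv(ft, K = 51), "cannot exceed")
  one_pos <- ft
  one_pos$label <- c(1L, rep(0L, 49))
  expect_error(
    kfold_cv(one_pos, K = 50, seed = 1),
    "both classes"
  )
})
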