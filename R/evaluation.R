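# Performance evaluation.
#
# ROC curves over score thresholds, trapezoidal AUC (equal to the
# Mann-Whitney statistic with ties counted 1/2), the Hanley-McNeil
# closed-form standard error of an AUC, a z test for the difference of two
# correlated AUCs, and K-fold cross-validation of the integrative model.

#' ROC curve of a scored binary classifier
#'
#' One operating point per unique score value (ties grouped at a single
#' threshold) plus the (0,0) sentinel.  With
#' `orientation = "higher_is_positive"` a case is called positive when its
#' score is >= the threshold; `"lower_is_positive"` reverses the
#' comparison (appropriate for p-value-like scores).
#'
#' @param scores numeric vector of finite classifier scores.
#' @param labels binary labels (0/1 or logical), 1 = experimentally
#'   supported.
#' @param orientation `"higher_is_positive"` (default) or
#'   `"lower_is_positive"`.
#' @return a `roc_curve` object: data frame with columns `threshold` (on
#'   the original score scale; the first row's sentinel threshold calls
#'   nothing positive), `fpr`, `tpr`.  Both rates are non-decreasing, from
#'   (0,0) to (1,1).
#' @seealso [auc()], [auc_estimate()]
#' @export
roc_curve <- function(scores, labels,
                      orientation = c("higher_is_positive", "lower_is_positive")) {
  orientation <- match.arg(orientation)
  y <- as.integer(as.logical(labels))
  if (length(scores) != length(y)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  if (any(!is.finite(scores))) {
    stop("scores must be finite", call. = FALSE)
  }
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("labels are single-class; need both positives and negatives",
      call. = FALSE
    )
  }
  s <- if (orientation == "lower_is_positive") -scores else scores
  ord <- order(s, decreasing = TRUE)
  s_sorted <- s[ord]
  y_sorted <- y[ord]
  # index of the last member of each tie group
  last <- c(which(diff(s_sorted) != 0), length(s_sorted))
  tp <- cumsum(y_sorted)[last]
  fp <- cumsum(1L - y_sorted)[last]
  thr <- s_sorted[last]
  if (orientation == "lower_is_positive") thr <- -thr
  out <- data.frame(
    threshold = c(if (orientation == "lower_is_positive") -Inf else Inf, thr),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
  structure(out,
    orientation = orientation, n_pos = n_pos, n_neg = n_neg,
    class = c("roc_curve", "data.frame")
  )
}

#' Area under a ROC curve
#'
#' Trapezoidal area under the curve; with ties grouped at single
#' thresholds this equals the Mann-Whitney two-sample statistic with tied
#' score pairs counted 1/2.
#'
#' @param curve a `roc_curve`.
#' @return the area estimate (a number in \[0, 1\]).
#' @export
auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
}

#' Hanley-McNeil standard error of an AUC
#'
#' Closed-form standard error of an area estimate, using the
#' exponential-model quantities `Q1 = theta / (2 - theta)` and
#' `Q2 = 2 * theta^2 / (1 + theta)`:
#' \deqn{SE = \sqrt{\frac{\theta(1-\theta) + (n_A-1)(Q_1-\theta^2) +
#'   (n_N-1)(Q_2-\theta^2)}{n_A n_N}}}
#' with `theta` the (plug-in) area and `n_A`, `n_N` the two class sizes.
#'
#' @param theta area in \[0, 1\] (the observed area is plugged in).
#' @param n_pos number of positives (`n_A`).
#' @param n_neg number of negatives (`n_N`).
#' @return a list with `q1`, `q2`, `se`.  `se` is exactly 0 at
#'   `theta` 0 or 1.
#' @references Hanley JA, McNeil BJ (1982) The meaning and use of the area
#'   under a receiver operating characteristic (ROC) curve. Radiology
#'   143:29-36.
#' @export
auc_se <- function(theta, n_pos, n_neg) {
  if (any(theta < 0 | theta > 1)) {
    stop("theta must lie in [0, 1]", call. = FALSE)
  }
  if (any(n_pos < 1) || any(n_neg < 1)) {
    stop("class sizes must be at least 1", call. = FALSE)
  }
  q1 <- theta / (2 - theta)
  q2 <- 2 * theta^2 / (1 + theta)
  var <- (theta * (1 - theta) +
    (n_pos - 1) * (q1 - theta^2) +
    (n_neg - 1) * (q2 - theta^2)) / (n_pos * n_neg)
  list(q1 = q1, q2 = q2, se = sqrt(pmax(var, 0)))
}

#' AUC with its Hanley-McNeil standard error
#'
#' Convenience wrapper: builds the ROC curve, takes the trapezoidal area
#' as the plug-in `theta`, and attaches the closed-form standard error.
#'
#' @inheritParams roc_curve
#' @return an `auc_estimate` object: list with `omega` (area estimate),
#'   `theta` (= omega), `q1`, `q2`, `n_pos`, `n_neg`, `se`.
#' @export
auc_estimate <- function(scores, labels,
                         orientation = c("higher_is_positive", "lower_is_positive")) {
  orientation <- match.arg(orientation)
  curve <- roc_curve(scores, labels, orientation)
  omega <- auc(curve)
  hm <- auc_se(omega, attr(curve, "n_pos"), attr(curve, "n_neg"))
  structure(
    list(
      omega = omega, theta = omega, q1 = hm$q1, q2 = hm$q2,
      n_pos = attr(curve, "n_pos"), n_neg = attr(curve, "n_neg"),
      se = hm$se
    ),
    class = "auc_estimate"
  )
}

#' Compare two correlated AUCs
#'
#' z test for the difference of two areas measured on the same cases:
#' `se_diff = sqrt(se1^2 + se2^2 - 2 r se1 se2)`,
#' `z = (omega1 - omega2) / se_diff`, with a two-sided normal p-value.
#'
#' @param est_a,est_b `auc_estimate` objects.
#' @param r estimated correlation between the two area estimates (see
#'   [estimate_r()]).
#' @return an `auc_comparison` object: list with `omega1`, `omega2`, `r`,
#'   `se_diff`, `z`, `p_two_sided`.
#' @details A zero `se_diff` with unequal areas is an error; with equal
#'   areas the statistic is defined as `z = 0`.
#' @references Hanley JA, McNeil BJ (1983) A method of comparing the areas
#'   under receiver operating characteristic curves derived from the same
#'   cases. Radiology 148:839-843.
#' @export
compare_auc <- function(est_a, est_b, r) {
  if (!(r >= -1 && r <= 1)) {
    stop("r must lie in [-1, 1]", call. = FALSE)
  }
  se_diff <- sqrt(max(est_a$se^2 + est_b$se^2 - 2 * r * est_a$se * est_b$se, 0))
  diff <- est_a$omega - est_b$omega
  if (se_diff == 0) {
    if (diff != 0) {
      stop("zero standard error for a non-zero AUC difference", call. = FALSE)
    }
    z <- 0
  } else {
    z <- diff / se_diff
  }
  structure(
    list(
      omega1 = est_a$omega, omega2 = est_b$omega, r = r,
      se_diff = se_diff, z = z,
      p_two_sided = 2 * stats::pnorm(-abs(z))
    ),
    class = "auc_comparison"
  )
}

# DeLong placement values: for each positive, the fraction of negatives it
# outscores (ties 1/2); and symmetrically for each negative.
delong_placements <- function(scores, y) {
  pos <- scores[y == 1L]
  neg <- scores[y == 0L]
  v10 <- vapply(
    pos, function(x) mean((x > neg) + 0.5 * (x == neg)), numeric(1L)
  )
  v01 <- vapply(
    neg, function(x) mean((pos > x) + 0.5 * (pos == x)), numeric(1L)
  )
  list(v10 = v10, v01 = v01)
}

#' Correlation between two AUC estimates on the same cases
#'
#' Two estimators of the correlation `r` entering [compare_auc()]:
#' `"average"` (default) averages the Pearson correlation of the two score
#' vectors within positives and within negatives (the classical
#' average-correlation approximation); `"delong"` derives `r` from the
#' DeLong covariance of the two area estimates (placement values).
#'
#' @param scores_a,scores_b score vectors of the two classifiers, aligned
#'   to the same rows.
#' @param labels binary labels shared by both classifiers.
#' @param method `"average"` or `"delong"`.
#' @return the estimated correlation.
#' @references DeLong ER, DeLong DM, Clarke-Pearson DL (1988) Comparing
#'   the areas under two or more correlated receiver operating
#'   characteristic curves. Biometrics 44:837-845.
#' @export
estimate_r <- function(scores_a, scores_b, labels,
                       method = c("average", "delong")) {
  method <- match.arg(method)
  y <- as.integer(as.logical(labels))
  if (length(scores_a) != length(y) || length(scores_b) != length(y)) {
    stop("score vectors must be aligned to the labels", call. = FALSE)
  }
  if (sum(y == 1L) < 3L || sum(y == 0L) < 3L) {
    stop("need at least 3 rows in each class", call. = FALSE)
  }
  if (identical(scores_a, scores_b)) {
    return(1)
  }
  if (method == "average") {
    r_pos <- stats::cor(scores_a[y == 1L], scores_b[y == 1L])
    r_neg <- stats::cor(scores_a[y == 0L], scores_b[y == 0L])
    (r_pos + r_neg) / 2
  } else {
    a <- delong_placements(scores_a, y)
    b <- delong_placements(scores_b, y)
    m <- sum(y == 1L)
    n <- sum(y == 0L)
    cov_ab <- stats::cov(a$v10, b$v10) / m + stats::cov(a$v01, b$v01) / n
    var_a <- stats::var(a$v10) / m + stats::var(a$v01) / n
    var_b <- stats::var(b$v10) / m + stats::var(b$v01) / n
    cov_ab / sqrt(var_a * var_b)
  }
}

#' K-fold cross-validation of the integrative model
#'
#' Randomly partitions the feature table into K near-equal folds, fits the
#' model on K-1 folds, predicts the held-out fold, and averages the
#' per-row prediction cost over all rows.  The default cost is the squared
#' difference between the label and the held-out predicted probability.
#'
#' @param table a `feature_table`.
#' @param feature_subset features to fit (default all four).
#' @param K number of folds (>= 2, <= number of rows).
#' @param seed integer seed; the partition (and hence the result) is fully
#'   reproducible given the seed.
#' @param cost `"squared"` (default) or `"misclass"` (0/1 error at the 0.5
#'   probability cutoff).
#' @param ... passed on to [fit_model()].
#' @return a `cv_result` object: list with `K`, `seed`, `fold_sizes`,
#'   `mean_prediction_error`, `cost`.
#' @details Partitions in which some training fold is single-class are
#'   redrawn (up to 100 times) before erroring.  Fold sizes differ by at
#'   most one and the folds partition all rows.
#' @export
kfold_cv <- function(table, feature_subset = FEATURE_NAMES, K = 10L,
                     seed = 1L, cost = c("squared", "misclass"), ...) {
  cost <- match.arg(cost)
  n <- nrow(table)
  K <- as.integer(K)
  if (K < 2L) stop("K must be at least 2", call. = FALSE)
  if (K > n) stop("K cannot exceed the number of rows", call. = FALSE)
  y <- as.numeric(table$label)

  fold <- with_seed(seed, {
    assignment <- NULL
    for (try in seq_len(100L)) {
      cand <- sample(rep(seq_len(K), length.out = n))
      ok <- all(vapply(seq_len(K), function(k) {
        length(unique(y[cand != k])) == 2L
      }, logical(1L)))
      if (ok) {
        assignment <- cand
        break
      }
    }
    assignment
  })
  if (is.null(fold)) {
    stop(
      "could not draw a partition with both classes in every training fold",
      call. = FALSE
    )
  }

  pred <- numeric(n)
  for (k in seq_len(K)) {
    test <- fold == k
    fit <- fit_model(table[!test, , drop = FALSE],
      feature_subset = feature_subset, ...
    )
    pred[test] <- predict_score(fit, table[test, , drop = FALSE])
  }
  err <- switch(cost,
    squared = mean((y - pred)^2),
    misclass = mean(y != as.numeric(pred > 0.5))
  )
  structure(
    list(
      K = K, seed = as.integer(seed),
      fold_sizes = as.integer(tabulate(fold, nbins = K)),
      mean_prediction_error = err, cost = cost
    ),
    class = "cv_result"
  )
}
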