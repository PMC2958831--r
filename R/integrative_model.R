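# The integrative sigmoidal model.
#
# The integrated target score is p = 1 / (1 + exp(-(b0 + sum_k b_k x_k))):
# a logistic regression of experimental support on the per-site feature
# vector, fitted by plain maximum likelihood (iteratively reweighted least
# squares with a Newton step and step-halving).  Features enter raw -- the
# expression p-value untransformed, the miRanda score on its native scale
# -- so each beta_k is directly interpretable as the contribution of its
# source.  No regularization is applied unless separation is detected, in
# which case a tiny ridge penalty (lambda = 1e-6) stabilizes the fit and
# the event is flagged.

#' Construct a model-fit object from known coefficients
#'
#' Builds the object returned by [fit_model()] directly from a coefficient
#' vector, e.g. when scoring with externally estimated or persisted
#' coefficients.
#'
#' @param feature_names character vector of feature names, in order.
#' @param beta numeric vector: intercept followed by one coefficient per
#'   feature.
#' @param beta_se optional standard errors (same length as `beta`).
#' @param converged,n_iterations,log_likelihood,training_prevalence,separation,ridge_lambda,n_obs
#'   optional fit metadata.
#' @return an object of class `mirfuse_fit`.
#' @export
model_fit <- function(feature_names, beta, beta_se = rep(NA_real_, length(beta)),
                      converged = NA, n_iterations = NA_integer_,
                      log_likelihood = NA_real_,
                      training_prevalence = NA_real_,
                      separation = FALSE, ridge_lambda = 0,
                      n_obs = NA_integer_) {
  if (length(beta) != length(feature_names) + 1L) {
    stop("beta must have one intercept plus one coefficient per feature",
      call. = FALSE
    )
  }
  names(beta) <- names(beta_se) <- c("(Intercept)", feature_names)
  structure(
    list(
      feature_names = feature_names,
      beta = beta,
      beta_se = beta_se,
      converged = converged,
      n_iterations = n_iterations,
      log_likelihood = log_likelihood,
      training_prevalence = training_prevalence,
      separation = separation,
      ridge_lambda = ridge_lambda,
      n_obs = n_obs
    ),
    class = "mirfuse_fit"
  )
}

# Penalized log-likelihood (lambda = 0 gives the plain likelihood).
logistic_loglik <- function(X, y, w, beta, lambda) {
  eta <- drop(X %*% beta)
  sum(w * (y * eta - log1pexp(eta))) - 0.5 * lambda * sum(beta[-1L]^2)
}

# Newton / IRLS with step-halving.  Returns beta, the observed-information
# SEs, convergence metadata.
irls_logistic <- function(X, y, w, tol, max_iter, lambda) {
  k <- ncol(X)
  beta <- numeric(k)
  penalty <- diag(c(0, rep(lambda, k - 1L)), nrow = k)
  ll <- logistic_loglik(X, y, w, beta, lambda)
  converged <- FALSE
  it <- 0L
  H <- NULL
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    W <- w * pmax(p * (1 - p), 1e-10)
    g <- drop(crossprod(X, w * (y - p))) - c(0, lambda * beta[-1L])
    H <- crossprod(X, X * W) + penalty
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) {
      return(list(
        beta = beta, H = H, log_likelihood = ll,
        converged = FALSE, n_iterations = it, singular = TRUE
      ))
    }
    ll_new <- logistic_loglik(X, y, w, beta + step, lambda)
    halvings <- 0L
    while ((!is.finite(ll_new) || ll_new < ll - 1e-12) && halvings < 30L) {
      step <- step / 2
      ll_new <- logistic_loglik(X, y, w, beta + step, lambda)
      halvings <- halvings + 1L
    }
    beta <- beta + step
    rel <- abs(ll_new - ll) / (abs(ll) + 0.1)
    ll <- ll_new
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  # Observed information at the solution for the SEs.
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  W <- w * pmax(p * (1 - p), 1e-10)
  H <- crossprod(X, X * W) + penalty
  list(
    beta = beta, H = H, log_likelihood = ll,
    converged = converged, n_iterations = it, singular = FALSE
  )
}

#' Fit the integrative logistic model
#'
#' Maximum-likelihood logistic regression of the binary support label on a
#' subset of the assembled features, with intercept.  Convergence is
#' declared when the relative change in log-likelihood falls below `tol`
#' (default 1e-8) within `max_iter` (default 50) Newton iterations.
#'
#' @param table a `feature_table` from [assemble_features()].
#' @param feature_subset character vector of feature columns to use
#'   (default all four).
#' @param weights optional per-row case weights (exploratory; the default
#'   fits the raw likelihood).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum number of iterations.
#' @param transform_expr if `TRUE`, enter `x_expr` as -log10(p) instead of
#'   the raw p-value (off by default; the canonical model uses raw scores).
#' @return a `mirfuse_fit` object with elements `feature_names`, `beta`
#'   (named, intercept first), `beta_se`, `converged`, `n_iterations`,
#'   `log_likelihood`, `training_prevalence`, `separation`,
#'   `ridge_lambda`, `n_obs`.
#' @details Single-class labels and constant features are errors.  Any
#'   |beta| exceeding 15 triggers a complete/quasi-complete separation
#'   warning; the model is then refitted with a tiny ridge penalty
#'   (lambda = 1e-6) and still returned, with `separation = TRUE`.
#' @seealso [predict_score()], [score_gradient()], [fit_reduced_models()]
#' @export
fit_model <- function(table, feature_subset = FEATURE_NAMES,
                      weights = NULL, tol = 1e-8, max_iter = 50L,
                      transform_expr = FALSE) {
  if (length(feature_subset) == 0L) {
    stop("feature_subset must name at least one feature", call. = FALSE)
  }
  missing_cols <- setdiff(c(feature_subset, "label"), colnames(table))
  if (length(missing_cols)) {
    stop("table is missing column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  y <- as.numeric(table$label)
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("label must be binary 0/1", call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop("labels are single-class; need both positives and negatives",
      call. = FALSE
    )
  }
  feats <- as.matrix(table[, feature_subset, drop = FALSE])
  if (transform_expr && "x_expr" %in% feature_subset) {
    pe <- feats[, "x_expr"]
    feats[, "x_expr"] <- -log10(pmax(pe, .Machine$double.xmin))
  }
  if (anyNA(feats)) {
    stop("features contain missing values; assemble with a missing policy",
      call. = FALSE
    )
  }
  const <- apply(feats, 2L, function(v) max(v) == min(v))
  if (any(const)) {
    stop("constant feature(s): ",
      paste(feature_subset[const], collapse = ", "),
      call. = FALSE
    )
  }
  w <- if (is.null(weights)) rep(1, length(y)) else as.numeric(weights)
  if (length(w) != length(y) || any(w < 0)) {
    stop("weights must be non-negative, one per row", call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, feats)

  res <- irls_logistic(X, y, w, tol, max_iter, lambda = 0)
  separation <- res$singular || any(abs(res$beta) > 15)
  ridge_lambda <- 0
  if (separation) {
    warning(
      "possible complete or quasi-complete separation detected; ",
      "refitting with ridge penalty lambda = 1e-6",
      call. = FALSE
    )
    ridge_lambda <- 1e-6
    res <- irls_logistic(X, y, w, tol, max_iter, lambda = ridge_lambda)
  }
  se <- sqrt(diag(tryCatch(solve(res$H), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })))
  model_fit(
    feature_names = feature_subset,
    beta = res$beta,
    beta_se = se,
    converged = res$converged,
    n_iterations = res$n_iterations,
    log_likelihood = res$log_likelihood,
    training_prevalence = stats::weighted.mean(y, w),
    separation = separation,
    ridge_lambda = ridge_lambda,
    n_obs = length(y)
  )
}

#' @export
print.mirfuse_fit <- function(x, ...) {
  cat("Integrative logistic target-scoring model\n")
  cat(
    "  features:", paste(x$feature_names, collapse = ", "), "\n",
    " n =", x$n_obs, " prevalence =",
    format(x$training_prevalence, digits = 4), "\n"
  )
  coefs <- data.frame(
    estimate = x$beta, std_error = x$beta_se,
    row.names = names(x$beta)
  )
  print(coefs, digits = 4)
  cat(
    "  converged:", x$converged, "in", x$n_iterations,
    "iterations; log-likelihood", format(x$log_likelihood, digits = 6), "\n"
  )
  if (isTRUE(x$separation)) {
    cat(
      "  note: separation detected; ridge lambda =",
      format(x$ridge_lambda), "\n"
    )
  }
  invisible(x)
}

# Coerce prediction input to a numeric matrix over the fit's features.
feature_matrix <- function(fit, x) {
  if (is.numeric(x) && is.null(dim(x))) {
    x <- as.data.frame(as.list(x))
  }
  x <- as.data.frame(x)
  missing_cols <- setdiff(fit$feature_names, colnames(x))
  if (length(missing_cols)) {
    stop("missing feature(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  m <- as.matrix(x[, fit$feature_names, drop = FALSE])
  if (anyNA(m) || any(!is.finite(m))) {
    stop("feature values must be finite", call. = FALSE)
  }
  m
}

#' Score sites with a fitted model
#'
#' Applies the sigmoidal transformation
#' `p = 1 / (1 + exp(-(b0 + sum_k b_k x_k)))` to one or more feature
#' vectors.
#'
#' @param fit a `mirfuse_fit`.
#' @param x a named numeric vector, data frame or `feature_table`
#'   covering `fit$feature_names`.
#' @return numeric vector of integrated scores in (0, 1).
#' @export
predict_score <- function(fit, x) {
  m <- feature_matrix(fit, x)
  eta <- drop(fit$beta[1L] + m %*% fit$beta[-1L])
  unname(stats::plogis(eta))
}

#' Sensitivity of the integrated score to one feature
#'
#' The derivative of the integrated score with respect to feature `k`:
#' `dp/dx_k = beta_k * p * (1 - p)`, with `p = predict_score(fit, x)`.
#' Largest where the model is least certain (p near 0.5) and zero in the
#' saturated tails.
#'
#' @param fit a `mirfuse_fit`.
#' @param x feature vector(s) as in [predict_score()].
#' @param feature name of the feature to differentiate with respect to.
#' @return numeric vector of derivatives.
#' @export
score_gradient <- function(fit, x, feature) {
  if (!(feature %in% fit$feature_names)) {
    stop("unknown feature '", feature, "'", call. = FALSE)
  }
  p <- predict_score(fit, x)
  unname(fit$beta[feature] * p * (1 - p))
}

#' Fit reduced models on identical rows
#'
#' Fits one model per requested feature subset, all on the same rows
#' (rows where any feature in the union of the requested subsets was
#' imputed are dropped first), so that training performance is comparable
#' across subsets.
#'
#' @param table a `feature_table`.
#' @param subsets list of character vectors of feature names.
#' @param ... passed on to [fit_model()].
#' @return a list with one element per subset: `list(subset =, fit =)`.
#' @export
fit_reduced_models <- function(table, subsets, ...) {
  if (length(subsets) == 0L) {
    return(list())
  }
  if (any(lengths(subsets) == 0L)) {
    stop("each feature subset must be non-empty", call. = FALSE)
  }
  union_feats <- unique(unlist(subsets))
  if (!is.null(table$imputed_flags)) {
    imputed <- strsplit(table$imputed_flags, ",", fixed = TRUE)
    drop <- vapply(
      imputed, function(f) any(f %in% union_feats), logical(1L)
    )
    table <- table[!drop, , drop = FALSE]
  }
  lapply(subsets, function(s) {
    list(subset = s, fit = fit_model(table, feature_subset = s, ...))
  })
}

#' Persist a fitted model as a plain-text key-value file
#'
#' @param fit a `mirfuse_fit`.
#' @param path output path.
#' @param comments optional character vector written as leading '#' lines.
#' @return `path`, invisibly.
#' @export
write_model_fit <- function(fit, path, comments = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comments) && length(comments) > 0L) {
    writeLines(paste0("# ", comments), con)
  }
  kv <- c(
    feature_names = paste(fit$feature_names, collapse = ","),
    beta = paste(fmt_num(unname(fit$beta)), collapse = ","),
    beta_se = paste(fmt_num(unname(fit$beta_se)), collapse = ","),
    converged = as.character(fit$converged),
    n_iterations = as.character(fit$n_iterations),
    log_likelihood = fmt_num(fit$log_likelihood),
    training_prevalence = fmt_num(fit$training_prevalence),
    separation = as.character(fit$separation),
    ridge_lambda = fmt_num(fit$ridge_lambda),
    n_obs = as.character(fit$n_obs)
  )
  writeLines(paste(names(kv), kv, sep = "\t"), con)
  invisible(path)
}

#' Read a persisted model
#'
#' @param path path to a file written by [write_model_fit()].
#' @return a `mirfuse_fit`.
#' @export
read_model_fit <- function(path) {
  tb <- read_tsv_rows(path)
  rows <- c(list(tb$header), tb$rows)
  kv <- stats::setNames(
    vapply(rows, function(r) if (length(r) > 1L) r[2L] else "", ""),
    vapply(rows, `[[`, "", 1L)
  )
  split_num <- function(s) as.numeric(strsplit(s, ",", fixed = TRUE)[[1L]])
  model_fit(
    feature_names = strsplit(kv[["feature_names"]], ",", fixed = TRUE)[[1L]],
    beta = split_num(kv[["beta"]]),
    beta_se = split_num(kv[["beta_se"]]),
    converged = as.logical(kv[["converged"]]),
    n_iterations = as.integer(kv[["n_iterations"]]),
    log_likelihood = as.numeric(kv[["log_likelihood"]]),
    training_prevalence = as.numeric(kv[["training_prevalence"]]),
    separation = as.logical(kv[["separation"]]),
    ridge_lambda = as.numeric(kv[["ridge_lambda"]]),
    n_obs = as.integer(kv[["n_obs"]])
  )
}
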