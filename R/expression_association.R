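# Expression-based association scoring.
#
# A candidate miRNA-gene pair is scored by ordinary least squares of gene
# expression on miRNA expression across samples (fitted with stats::lm, a
# simple two-parameter model: intercept + slope).  Because miRNAs
# down-regulate their targets, only a *negative* slope counts as support:
# the expression score is the two-sided regression p-value when the slope
# is negative and 1 otherwise.

#' Regress gene expression on miRNA expression for one pair
#'
#' Ordinary least squares of `gene_expr` on `mirna_expr` (with intercept),
#' fitted with [stats::lm()].  The p-value is the two-sided t test on the
#' slope with `n - 2` degrees of freedom.
#'
#' @param mirna_expr numeric vector of log2 miRNA expression, one value per
#'   sample.  If both vectors are named, they are aligned on the
#'   intersection of their names.
#' @param gene_expr numeric vector of log2 gene expression on the same
#'   samples.
#' @return a list with elements `slope`, `p_value`, `n_samples`.
#' @details At least 3 shared samples are required (one residual degree of
#'   freedom beyond intercept and slope).  A constant miRNA vector is a
#'   "degenerate predictor" error.  A perfect fit (zero residual) reports
#'   `p_value = 0`; a constant gene vector reports slope 0 and
#'   `p_value = 1`.
#' @examples
#' x <- c(8, 9, 10, 11, 12, 13)
#' fit_pair_regression(x, -x + 5)
#' @export
fit_pair_regression <- function(mirna_expr, gene_expr) {
  if (!is.null(names(mirna_expr)) && !is.null(names(gene_expr))) {
    shared <- intersect(names(mirna_expr), names(gene_expr))
    mirna_expr <- mirna_expr[shared]
    gene_expr <- gene_expr[shared]
  } else if (length(mirna_expr) != length(gene_expr)) {
    stop("mirna_expr and gene_expr must cover the same samples",
      call. = FALSE
    )
  }
  n <- length(mirna_expr)
  if (n < 3L) {
    stop("need at least 3 shared samples, found ", n, call. = FALSE)
  }
  if (anyNA(mirna_expr) || anyNA(gene_expr)) {
    stop("missing expression values are not allowed", call. = FALSE)
  }
  m <- as.numeric(mirna_expr)
  g <- as.numeric(gene_expr)
  if (max(m) == min(m)) {
    stop("degenerate predictor: miRNA expression is constant", call. = FALSE)
  }
  tss <- sum((g - mean(g))^2)
  if (tss == 0) {
    return(list(slope = 0, p_value = 1, n_samples = n))
  }
  fit <- stats::lm(g ~ m)
  slope <- unname(stats::coef(fit)[2L])
  rss <- sum(stats::residuals(fit)^2)
  if (rss <= 1e-12 * tss) {
    # zero residual up to floating point: the fit is perfect
    p <- 0
  } else {
    sxx <- sum((m - mean(m))^2)
    se <- sqrt(rss / (n - 2) / sxx)
    p <- 2 * stats::pt(-abs(slope / se), df = n - 2)
  }
  list(slope = slope, p_value = p, n_samples = n)
}

#' Expression score from a slope and p-value
#'
#' The expression-based target score: the regression p-value when the
#' fitted slope is strictly negative (expression supports repression),
#' and 1 otherwise.  Vectorized.
#'
#' @param slope fitted regression slope(s).
#' @param p_value two-sided p-value(s) in \[0, 1\].
#' @return numeric vector of scores in \[0, 1\].
#' @examples
#' expression_score(c(-0.5, 0.5, 0), c(0.01, 0.01, 0.4))
#' @export
expression_score <- function(slope, p_value) {
  if (any(p_value < 0 | p_value > 1, na.rm = TRUE)) {
    stop("p_value must lie in [0, 1]", call. = FALSE)
  }
  ifelse(slope < 0, p_value, 1)
}

#' Score a list of miRNA-gene pairs by expression association
#'
#' Runs [fit_pair_regression()] for every requested pair over the
#' intersection of sample ids of the two matrices and attaches the
#' expression score of [expression_score()].
#'
#' @param mirna_mat numeric matrix of miRNA expression (entities x
#'   samples), e.g. from [read_expression_matrix()].
#' @param gene_mat numeric matrix of gene expression (entities x samples).
#' @param pairs data frame (or 2-column matrix) with columns `mirna_id`,
#'   `gene_id`.
#' @param adjust if `TRUE`, append a Benjamini-Hochberg adjusted p-value
#'   column `p_adjust` for reporting; it is never used as a model feature.
#' @return a data frame with columns `mirna_id`, `gene_id`, `n_samples`,
#'   `slope`, `p_value`, `expr_score` (and optionally `p_adjust`), one row
#'   per pair in input order.  Pairs whose miRNA row is constant are
#'   skipped with a warning and excluded from the output.
#' @examples
#' mir <- matrix(rnorm(12), 2, 6,
#'   dimnames = list(c("hsa-miR-1", "hsa-miR-2"), paste0("S", 1:6))
#' )
#' gen <- matrix(rnorm(12), 2, 6,
#'   dimnames = list(c("GENEA", "GENEB"), paste0("S", 1:6))
#' )
#' pairs <- data.frame(
#'   mirna_id = c("hsa-miR-1", "hsa-miR-2"),
#'   gene_id = c("GENEA", "GENEB")
#' )
#' associate_pairs(mir, gen, pairs)
#' @export
associate_pairs <- function(mirna_mat, gene_mat, pairs, adjust = FALSE) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!all(c("mirna_id", "gene_id") %in% colnames(pairs))) {
    colnames(pairs)[1:2] <- c("mirna_id", "gene_id")
  }
  if (nrow(pairs) == 0L) {
    out <- data.frame(
      mirna_id = character(0), gene_id = character(0),
      n_samples = integer(0), slope = numeric(0),
      p_value = numeric(0), expr_score = numeric(0),
      stringsAsFactors = FALSE
    )
    return(out)
  }
  unknown_m <- setdiff(unique(pairs$mirna_id), rownames(mirna_mat))
  unknown_g <- setdiff(unique(pairs$gene_id), rownames(gene_mat))
  if (length(unknown_m) || length(unknown_g)) {
    stop(
      "unknown identifier(s): ",
      paste(c(unknown_m, unknown_g), collapse = ", "),
      call. = FALSE
    )
  }
  shared <- intersect(colnames(mirna_mat), colnames(gene_mat))
  if (length(shared) < 3L) {
    stop(
      "matrices share only ", length(shared),
      " sample id(s); need at least 3",
      call. = FALSE
    )
  }
  mm <- mirna_mat[, shared, drop = FALSE]
  gm <- gene_mat[, shared, drop = FALSE]
  n <- nrow(pairs)
  slope <- p_value <- numeric(n)
  skip <- logical(n)
  for (i in seq_len(n)) {
    mrow <- mm[pairs$mirna_id[i], ]
    if (max(mrow) == min(mrow)) {
      warning(
        "skipping pair (", pairs$mirna_id[i], ", ", pairs$gene_id[i],
        "): constant miRNA expression",
        call. = FALSE
      )
      skip[i] <- TRUE
      next
    }
    fit <- fit_pair_regression(mrow, gm[pairs$gene_id[i], ])
    slope[i] <- fit$slope
    p_value[i] <- fit$p_value
  }
  out <- data.frame(
    mirna_id = pairs$mirna_id[!skip],
    gene_id = pairs$gene_id[!skip],
    n_samples = rep(length(shared), sum(!skip)),
    slope = slope[!skip],
    p_value = p_value[!skip],
    stringsAsFactors = FALSE
  )
  out$expr_score <- expression_score(out$slope, out$p_value)
  if (adjust) {
    out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  }
  rownames(out) <- NULL
  out
}

#' Gene-level expression score
#'
#' Collapses the associations of one miRNA-gene pair across multiple
#' transcripts or probes to a single gene-level score: the minimum of the
#' member expression scores.
#'
#' @param associations data frame with columns `mirna_id`, `gene_id`,
#'   `expr_score`, all rows belonging to the same miRNA and gene.
#' @return the minimum `expr_score`.
#' @export
gene_level_score <- function(associations) {
  if (nrow(associations) < 1L) {
    stop("need at least one association", call. = FALSE)
  }
  if (length(unique(associations$gene_id)) != 1L) {
    stop("mixed gene ids in gene-level aggregation", call. = FALSE)
  }
  if (length(unique(associations$mirna_id)) != 1L) {
    stop("mixed miRNA ids in gene-level aggregation", call. = FALSE)
  }
  min(associations$expr_score)
}
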