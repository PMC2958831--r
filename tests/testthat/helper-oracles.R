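# Independent oracles and small fixture builders used across tests.
# Each oracle is deliberately written as a direct transcription of the
# defining formula, independent of the package's implementation path.

# Mann-Whitney AUC by exhaustive pair counting, ties counted 1/2.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + (p > n) + 0.5 * (p == n)
    }
  }
  total / (length(pos) * length(neg))
}

# Simple linear regression via the textbook normal equations, with the
# two-sided slope t test.
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  rss <- sum((y - intercept - slope * x)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  t <- slope / se
  list(slope = slope, p_value = 2 * stats::pt(-abs(t), n - 2))
}

# Hanley-McNeil AUC standard error, re-derived arithmetic.
oracle_hanley_se <- function(theta, n_a, n_n) {
  q1 <- theta / (2 - theta)
  q2 <- (2 * theta * theta) / (1 + theta)
  num <- theta - theta * theta +
    (n_a - 1) * (q1 - theta * theta) +
    (n_n - 1) * (q2 - theta * theta)
  list(q1 = q1, q2 = q2, se = sqrt(num / (n_a * n_n)))
}

# Write TSV content (a character vector of lines) to a temp file.
tmp_tsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# A small deterministic feature table with an informative structure.
tiny_feature_table <- function(n = 200, seed = 1) {
  simulate_feature_table(n, beta = c(-2, 0.15, 1, -1.5, -1), seed = seed)
}

# One default-condition synthetic run: feature table assembled from
# expression, predictions and gold standard.
assembled_synthetic <- function(seed, missing_policy = "impute_neutral",
                                coverage = 0.8, contamination = 0.01, ...) {
  truth <- simulation_truth(seed = seed, ...)
  ds <- simulate_dataset(truth, coverage = coverage, contamination = contamination)
  all_preds <- do.call(rbind, unname(ds$predictions))
  pairs <- unique(all_preds[, c("mirna_id", "gene_id")])
  assoc <- associate_pairs(ds$mirna_expr, ds$gene_expr, pairs)
  list(
    truth = truth,
    dataset = ds,
    associations = assoc,
    features = assemble_features(
      ds$predictions, assoc, build_gold_standard(ds$gold, "tarbase"),
      missing_policy = missing_policy
    )
  )
}

single_feature_aucs <- function(features) {
  orientations <- c(
    x_miranda = "higher_is_positive", x_pictar = "higher_is_positive",
    x_targetscan = "higher_is_positive", x_expr = "lower_is_positive"
  )
  vapply(names(orientations), function(f) {
    auc_estimate(features[[f]], features$label, orientations[[f]])$omega
  }, numeric(1))
}
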