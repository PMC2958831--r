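test_that("every generator is bit-reproducible under its seed", {
  t1 <- simulation_truth(
    n_mirna = 8, n_gene = 20, n_pairs = 60, n_true = 15, seed = 14
  )
  t2 <- simulation_truth(
    n_mirna = 8, n_gene = 20, n_pairs = 60, n_true = 15, seed = 14
  )
  expect_identical(t1, t2)
  expect_identical(
    generate_expression(t1, n_samples = 10),
    generate_expression(t2, n_samples = 10)
  )
  expect_identical(
    generate_prediction_tables(t1), generate_prediction_tables(t2)
  )
  expect_identical(generate_gold_standard(t1), generate_gold_standard(t2))
  # generation order does not matter: each stage draws from its own stream
  g_first <- generate_gold_standard(t1)
  e_after <- generate_expression(t1, n_samples = 10)
  expect_identical(e_after, generate_expression(t2, n_samples = 10))
  expect_identical(g_first, generate_gold_standard(t2))
})

test_that("without noise a regulated gene is an affine function of its miRNA", {
  truth <- simulation_truth(
    n_mirna = 2, n_gene = 2, n_pairs = 1, n_true = 1,
    effect_size = -1, seed = 24
  )
  expr <- generate_expression(truth, n_samples = 12, noise_sd = 0)
  pair <- truth$pairs[truth$pairs$is_true, ]
  g <- expr$gene[pair$gene_id, ]
  m <- expr$mirna[pair$mirna_id, ]
  fit <- stats::lm(g ~ m)
  expect_equal(unname(stats::coef(fit)[2]), -1, tolerance = 1e-12)
  expect_lt(max(abs(stats::residuals(fit))), 1e-10)
})

test_that("unregulated expression matrices are statistically independent", {
  truth <- simulation_truth(
    n_mirna = 10, n_gene = 100, n_pairs = 100, n_true = 0, seed = 34
  )
  expr <- generate_expression(truth, n_samples = 58)
  cors <- vapply(seq_len(100), function(i) {
    stats::cor(
      expr$mirna[truth$pairs$mirna_id[i], ],
      expr$gene[truth$pairs$gene_id[i], ]
    )
  }, numeric(1))
  expect_lt(mean(abs(cors)), 0.2) # null |r| ~ 0.8/sqrt(58)
})

test_that("generator preconditions are enforced", {
  expect_error(simulation_truth(effect_size = 0.5), "<= 0")
  expect_error(
    simulation_truth(informativeness = c(
      miranda = 1.5, pictar = 0.5, targetscan = 0.5
    )),
    "\\[0, 1\\]"
  )
  expect_error(
    simulation_truth(n_mirna = 2, n_gene = 2, n_pairs = 10),
    "grid"
  )
  truth <- simulation_truth(
    n_mirna = 5, n_gene = 5, n_pairs = 10, n_true = 2, seed = 1
  )
  expect_error(generate_expression(truth, n_samples = 2), "at least 3")
  expect_error(generate_expression(truth, noise_sd = -1), "non-negative")
  expect_error(generate_gold_standard(truth, coverage = 1.4), "\\[0, 1\\]")
})

test_that("an uninformative source scores true and false pairs alike", {
  truth <- simulation_truth(
    n_mirna = 40, n_gene = 200, n_pairs = 4000, n_true = 1000,
    informativeness = c(miranda = 0, pictar = 0.5, targetscan = 0.5),
    detect_prob_true = 1, detect_prob_false = 1,
    max_sites_per_pair = 1, seed = 44
  )
  preds <- generate_prediction_tables(truth)$miranda
  truth_key <- paste(truth$pairs$mirna_id, truth$pairs$gene_id)
  is_true <- paste(preds$mirna_id, preds$gene_id) %in%
    truth_key[truth$pairs$is_true]
  ks <- suppressWarnings(
    stats::ks.test(preds$score[is_true], preds$score[!is_true])
  )
  expect_gt(ks$p.value, 0.01)
})

test_that("a maximally informative source separates pairs with AUC > 0.9", {
  truth <- simulation_truth(
    n_mirna = 20, n_gene = 100, n_pairs = 1000, n_true = 300,
    informativeness = c(miranda = 1, pictar = 1, targetscan = 1),
    detect_prob_true = 1, detect_prob_false = 1,
    max_sites_per_pair = 1, seed = 54
  )
  preds <- generate_prediction_tables(truth)
  truth_key <- paste(truth$pairs$mirna_id, truth$pairs$gene_id)
  for (src in names(preds)) {
    tab <- preds[[src]]
    is_true <- paste(tab$mirna_id, tab$gene_id) %in%
      truth_key[truth$pairs$is_true]
    expect_gt(auc(roc_curve(tab$score, is_true)), 0.9)
  }
})

test_that("PicTar scores stay inside the native range", {
  truth <- simulation_truth(
    n_mirna = 20, n_gene = 100, n_pairs = 1500, n_true = 500, seed = 64
  )
  pictar <- generate_prediction_tables(truth)$pictar
  expect_true(all(pictar$score >= 0 & pictar$score <= 1000))
  targetscan <- generate_prediction_tables(truth)$targetscan
  expect_true(all(targetscan$score >= 0 & targetscan$score <= 1))
})

test_that("gold-standard sampling honours coverage and contamination", {
  truth <- simulation_truth(
    n_mirna = 10, n_gene = 50, n_pairs = 200, n_true = 100, seed = 74
  )
  full <- generate_gold_standard(truth, coverage = 1, contamination = 0)
  truth_pairs <- truth$pairs[truth$pairs$is_true, ]
  expect_setequal(
    paste(full$mirna_id, full$gene_id),
    paste(truth_pairs$mirna_id, truth_pairs$gene_id)
  )

  empty <- generate_gold_standard(truth, coverage = 0, contamination = 0)
  expect_equal(nrow(empty), 0L)

  half <- generate_gold_standard(truth, coverage = 0.5, contamination = 0)
  expect_equal(nrow(half), 50L)
})

test_that("an empty gold standard forces the downstream single-class error", {
  env <- assembled_synthetic(
    seed = 84, n_mirna = 8, n_gene = 20, n_pairs = 60, n_true = 10
  )
  empty_gold <- generate_gold_standard(
    env$truth,
    coverage = 0, contamination = 0
  )
  ft <- assemble_features(
    env$dataset$predictions, env$associations,
    build_gold_standard(empty_gold, "tarbase")
  )
  expect_error(fit_model(ft), "single-class")
})

test_that("feature-table simulation reproduces its generating prevalence", {
  beta <- c(-2, 0.15, 1, -1.5, -1)
  ft <- simulate_feature_table(4000, beta = beta, seed = 94)
  expect_identical(ft, simulate_feature_table(4000, beta = beta, seed = 94))
  x <- as.matrix(ft[, c("x_miranda", "x_pictar", "x_targetscan", "x_expr")])
  expected <- mean(stats::plogis(drop(beta[1] + x %*% beta[-1])))
  expect_equal(mean(ft$label), expected, tolerance = 0.05)
})
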