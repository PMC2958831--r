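make_preds <- function(source, mirna, gene, site, score) {
  data.frame(
    mirna_id = mirna, gene_id = gene, site_id = site,
    source = source, score = score, stringsAsFactors = FALSE
  )
}

test_that("PicTar normalization divides by the maximum of 1000", {
  expect_equal(normalize_pictar(1000), 1.0)
  expect_equal(normalize_pictar(0), 0.0)
  expect_equal(normalize_pictar(500), 0.5)
  expect_error(normalize_pictar(1001), "1000")
  expect_error(normalize_pictar(-1), "non-negative")
})

test_that("gold-standard variants filter and union as documented", {
  entries <- data.frame(
    mirna_id = paste0("hsa-miR-", 1:5),
    gene_id = LETTERS[1:5],
    experiment_type = c(
      "individual", "high_throughput", "individual", "individual", "individual"
    ),
    provenance = ""
  )
  expect_equal(nrow(build_gold_standard(entries, "tarbase")$pairs), 5L)
  expect_equal(
    nrow(build_gold_standard(entries, "tarbase_no_highthroughput")$pairs), 4L
  )

  # union with expression-corroborated pairs below the threshold
  assoc <- data.frame(
    mirna_id = paste0("hsa-miR-", c(8, 9, 1)),
    gene_id = c("H", "I", "A"),
    expr_score = c(0.005, 0.5, 1)
  )
  two <- entries[1:2, ]
  gs <- build_gold_standard(two, "tarbase_plus_lcl",
    associations = assoc, lcl_p_threshold = 0.01
  )
  expect_equal(nrow(gs$pairs), 3L) # 2 curated + 1 corroborated (0.005 only)
  expect_error(
    build_gold_standard(two, "tarbase_plus_lcl"),
    "requires expression associations"
  )
})

test_that("the no-high-throughput variant is a subset of the full standard", {
  truth <- simulation_truth(
    n_mirna = 10, n_gene = 30, n_pairs = 100, n_true = 30, seed = 5
  )
  gold <- generate_gold_standard(truth, high_throughput_fraction = 0.5)
  full <- build_gold_standard(gold, "tarbase")$pairs
  noht <- build_gold_standard(gold, "tarbase_no_highthroughput")$pairs
  expect_true(all(
    paste(noht$mirna_id, noht$gene_id) %in% paste(full$mirna_id, full$gene_id)
  ))
})

test_that("assembly joins sites across sources and fills or drops missing", {
  preds <- rbind(
    make_preds("miranda", "hsa-miR-1", "A", "s1", 17),
    make_preds("pictar", "hsa-miR-1", "A", "s1", 800),
    make_preds("targetscan", "hsa-miR-1", "A", "s1", 0.9),
    make_preds("miranda", "hsa-miR-2", "B", "s1", 14)
  )
  assoc <- data.frame(
    mirna_id = c("hsa-miR-1", "hsa-miR-2"), gene_id = c("A", "B"),
    expr_score = c(0.02, 0.6)
  )
  gold <- build_gold_standard(
    data.frame(
      mirna_id = "hsa-miR-1", gene_id = "A",
      experiment_type = "individual", provenance = ""
    ),
    "tarbase"
  )

  ft <- assemble_features(preds, assoc, gold, "impute_neutral")
  expect_equal(nrow(ft), 2L)
  complete <- ft[ft$mirna_id == "hsa-miR-1", ]
  expect_equal(complete$x_miranda, 17)
  expect_equal(complete$x_pictar, 0.8)
  expect_equal(complete$x_targetscan, 0.9)
  expect_equal(complete$x_expr, 0.02)
  expect_equal(complete$imputed_flags, "")
  expect_equal(complete$label, 1L)

  only_miranda <- ft[ft$mirna_id == "hsa-miR-2", ]
  expect_equal(only_miranda$x_pictar, 0)
  expect_equal(only_miranda$x_targetscan, 0)
  expect_equal(only_miranda$x_expr, 0.6) # association exists: not imputed
  expect_equal(only_miranda$imputed_flags, "x_pictar,x_targetscan")
  expect_equal(only_miranda$label, 0L)

  cc <- assemble_features(preds, assoc, gold, "complete_cases")
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$mirna_id, "hsa-miR-1")

  # a site with no association at all imputes x_expr to the neutral 1
  ft2 <- assemble_features(preds, assoc[1, ], gold, "impute_neutral")
  expect_equal(ft2$x_expr[ft2$mirna_id == "hsa-miR-2"], 1)
})

test_that("assembly is invariant to input row order and counts rows exactly", {
  env <- assembled_synthetic(
    seed = 11, n_mirna = 10, n_gene = 40, n_pairs = 150, n_true = 30
  )
  preds <- do.call(rbind, unname(env$dataset$predictions))
  gold <- build_gold_standard(env$dataset$gold, "tarbase")

  shuffled <- preds[sample(nrow(preds)), ]
  a <- assemble_features(preds, env$associations, gold)
  b <- assemble_features(shuffled, env$associations, gold)
  expect_identical(a, b)

  # impute_neutral keeps the full site union; complete_cases never exceeds it
  n_sites <- length(unique(
    paste(preds$mirna_id, preds$gene_id, preds$site_id)
  ))
  expect_equal(nrow(a), n_sites)
  cc <- assemble_features(preds, env$associations, gold, "complete_cases")
  expect_lte(nrow(cc), n_sites)

  # label prevalence equals the gold coverage of the assembled pairs
  gold_keys <- paste(gold$pairs$mirna_id, gold$pairs$gene_id)
  expect_equal(
    sum(a$label), sum(paste(a$mirna_id, a$gene_id) %in% gold_keys)
  )
})

test_that("assembly rejects degenerate inputs", {
  expect_error(
    assemble_features(
      make_preds(character(0), character(0), character(0), character(0), numeric(0)),
      NULL,
      data.frame(mirna_id = "m", gene_id = "g", experiment_type = "individual")
    ),
    "empty row universe"
  )
  expect_error(
    assemble_features(
      make_preds("expression", "hsa-miR-1", "A", "s1", 0.5),
      NULL,
      data.frame(mirna_id = "m", gene_id = "g", experiment_type = "individual")
    ),
    "associations"
  )
})

test_that("pairwise correlations use the best score per shared pair", {
  a <- make_preds("miranda", rep("hsa-miR-1", 10), LETTERS[1:10],
    rep("s1", 10), 1:10
  )
  b <- make_preds("pictar", rep("hsa-miR-1", 10), LETTERS[1:10],
    rep("s1", 10), 2 * (1:10)
  )
  out <- pairwise_score_correlation(a, b)
  expect_equal(out$n_overlap, 10L)
  expect_equal(out$pearson_r, 1)
  expect_equal(out$spearman_rho, 1)

  b_neg <- b
  b_neg$score <- -a$score
  expect_equal(pairwise_score_correlation(a, b_neg)$pearson_r, -1)

  # multiple sites per pair: max wins
  a2 <- rbind(a, make_preds("miranda", "hsa-miR-1", "A", "s2", 100))
  out2 <- pairwise_score_correlation(a2, b)
  expect_equal(out2$n_overlap, 10L)
  expect_lt(out2$pearson_r, 1) # pair A now scores 100, breaking linearity

  expect_error(
    pairwise_score_correlation(a[1:2, ], b[1:2, ]),
    "insufficient overlap"
  )
})

test_that("independently simulated scores are uncorrelated", {
  set.seed(88)
  genes <- sprintf("G%04d", 1:1000)
  a <- make_preds("miranda", "hsa-miR-1", genes, "s1", rnorm(1000, 15, 2))
  b <- make_preds("targetscan", "hsa-miR-1", genes, "s1", rbeta(1000, 1, 3))
  out <- pairwise_score_correlation(a, b)
  expect_lt(abs(out$pearson_r), 0.1)
  expect_lt(abs(out$spearman_rho), 0.1)
})

test_that("binned score comparisons are normalized paired histograms", {
  set.seed(9)
  all_scores <- runif(500)
  sub <- sample(all_scores, 120)
  out <- binned_distribution_comparison(all_scores, sub, n_bins = 10)
  expect_equal(sum(out$prop_all), 1)
  expect_equal(sum(out$prop_gold), 1)
  expect_equal(nrow(out), 10L)

  same <- binned_distribution_comparison(all_scores, all_scores, 8)
  expect_equal(same$prop_all, same$prop_gold)

  # gold mass confined to the top bin
  top <- binned_distribution_comparison(
    seq(0, 1, length.out = 100), c(0.96, 0.99), n_bins = 10
  )
  expect_equal(top$prop_gold, c(rep(0, 9), 1))

  expect_error(
    binned_distribution_comparison(runif(10), numeric(0)),
    "empty gold subset"
  )
  expect_error(
    binned_distribution_comparison(runif(10), runif(2), n_bins = 1),
    "at least 2"
  )
})
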