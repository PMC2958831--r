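# Synthetic data with planted regulatory structure.
#
# The generator emulates the shape of the real inputs: log2 expression
# matrices over a few dozen cell-line samples, three per-source target
# prediction tables with source-native score ranges (miRanda alignment
# scores around 15, PicTar in [0, 1000], TargetScan P_CT in [0, 1]), and a
# partially covering, partially contaminated gold standard.  A single
# integer seed fully determines every generated artifact; the three
# generators draw from fixed offsets of that seed so they can be called in
# any order.

#' Define the ground truth of a simulation
#'
#' Samples a candidate universe of (miRNA, gene) pairs, plants a subset of
#' true regulatory pairs with negative effect sizes, assigns each pair its
#' target sites, and records how informative each prediction source is.
#'
#' Defaults mirror a desk-scale version of a typical cell-line study: 58
#' samples downstream, a few dozen miRNAs, 5000 candidate pairs of which
#' 200 are truly regulatory with a moderate log2-scale effect of -0.35 --
#' detectable across 58 samples but far from an oracle, like the other
#' sources.
#'
#' @param n_mirna number of miRNAs.
#' @param n_gene number of genes.
#' @param n_pairs number of candidate (miRNA, gene) pairs sampled from the
#'   `n_mirna * n_gene` grid.
#' @param n_true number of truly regulatory pairs among them.
#' @param effect_size slope of gene on miRNA expression for true pairs
#'   (log2 scale; must be <= 0, miRNAs repress their targets).
#' @param informativeness named vector in \[0, 1\] for sources `miranda`,
#'   `pictar`, `targetscan`: 0 = the source's scores carry no signal, 1 =
#'   maximal score shift for true pairs.
#' @param detect_prob_true,detect_prob_false probability that a source
#'   emits predictions for a true / false pair (sources are
#'   truth-enriched).
#' @param max_sites_per_pair each pair carries 1..`max_sites_per_pair`
#'   binding sites, shared across sources.
#' @param seed integer seed determining everything generated from this
#'   truth.
#' @return a `simulation_truth` object: list with `pairs` (data frame
#'   `mirna_id`, `gene_id`, `is_true`, `effect`, `n_sites`), `mirna_ids`,
#'   `gene_ids`, the source parameters and the seed.
#' @seealso [generate_expression()], [generate_prediction_tables()],
#'   [generate_gold_standard()], [simulate_dataset()]
#' @export
simulation_truth <- function(n_mirna = 40L, n_gene = 500L,
                             n_pairs = 5000L, n_true = 200L,
                             effect_size = -0.35,
                             informativeness = c(
                               miranda = 0.8, pictar = 0.8, targetscan = 0.8
                             ),
                             detect_prob_true = 0.8,
                             detect_prob_false = 0.5,
                             max_sites_per_pair = 2L,
                             seed = 1L) {
  if (n_pairs > n_mirna * n_gene) {
    stop("n_pairs exceeds the (miRNA x gene) grid", call. = FALSE)
  }
  if (n_true > n_pairs) {
    stop("n_true cannot exceed n_pairs", call. = FALSE)
  }
  if (any(effect_size > 0)) {
    stop("effect_size must be <= 0 (miRNAs repress their targets)",
      call. = FALSE
    )
  }
  need <- c("miranda", "pictar", "targetscan")
  if (!all(need %in% names(informativeness))) {
    stop("informativeness must name sources: ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(informativeness < 0 | informativeness > 1)) {
    stop("informativeness must lie in [0, 1]", call. = FALSE)
  }
  if (any(c(detect_prob_true, detect_prob_false) < 0) ||
    any(c(detect_prob_true, detect_prob_false) > 1)) {
    stop("detection probabilities must lie in [0, 1]", call. = FALSE)
  }

  mirna_ids <- sprintf("hsa-miR-%d", 100L + seq_len(n_mirna))
  gene_ids <- sprintf("GENE%04d", seq_len(n_gene))

  pairs <- with_seed(seed, {
    idx <- sample.int(n_mirna * n_gene, n_pairs)
    p <- data.frame(
      mirna_id = mirna_ids[((idx - 1L) %% n_mirna) + 1L],
      gene_id = gene_ids[((idx - 1L) %/% n_mirna) + 1L],
      stringsAsFactors = FALSE
    )
    p$is_true <- seq_len(n_pairs) %in% sample.int(n_pairs, n_true)
    p$effect <- ifelse(p$is_true, effect_size, 0)
    p$n_sites <- sample.int(max_sites_per_pair, n_pairs, replace = TRUE)
    p
  })

  structure(
    list(
      pairs = pairs,
      mirna_ids = mirna_ids,
      gene_ids = gene_ids,
      informativeness = informativeness[need],
      detect_prob_true = detect_prob_true,
      detect_prob_false = detect_prob_false,
      seed = as.integer(seed)
    ),
    class = "simulation_truth"
  )
}

#' Generate miRNA and gene expression matrices
#'
#' miRNA rows are Normal(baseline, 1) with baselines uniform on log2
#' intensities 6..12; each gene row is its baseline plus the sum of
#' `effect * miRNA expression` over its regulators plus Normal(0,
#' `noise_sd`) noise.
#'
#' @param truth a `simulation_truth`.
#' @param n_samples number of samples (>= 3; default 58).
#' @param noise_sd residual standard deviation of gene expression
#'   (default 1.0, a typical log2-scale residual spread across cell-line
#'   samples).
#' @return a list with numeric matrices `mirna` and `gene` (entities x
#'   samples) in the layout of [read_expression_matrix()].
#' @export
generate_expression <- function(truth, n_samples = 58L, noise_sd = 1.0) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (n_samples < 3L) stop("n_samples must be at least 3", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  n_mirna <- length(truth$mirna_ids)
  n_gene <- length(truth$gene_ids)
  sample_ids <- sprintf("S%03d", seq_len(n_samples))

  with_seed(truth$seed + 1L, {
    mirna_base <- stats::runif(n_mirna, 6, 12)
    mirna <- matrix(
      stats::rnorm(n_mirna * n_samples, mean = mirna_base, sd = 1),
      nrow = n_mirna, ncol = n_samples,
      dimnames = list(truth$mirna_ids, sample_ids)
    )
    gene_base <- stats::runif(n_gene, 6, 12)
    gene <- matrix(
      stats::rnorm(n_gene * n_samples, mean = gene_base, sd = noise_sd),
      nrow = n_gene, ncol = n_samples,
      dimnames = list(truth$gene_ids, sample_ids)
    )
    reg <- truth$pairs[truth$pairs$effect != 0, , drop = FALSE]
    for (i in seq_len(nrow(reg))) {
      g <- reg$gene_id[i]
      gene[g, ] <- gene[g, ] + reg$effect[i] * mirna[reg$mirna_id[i], ]
    }
    list(mirna = mirna, gene = gene)
  })
}

# Source-native score draw: n scores for true (is_true) / false pairs.
draw_source_scores <- function(source, is_true, info) {
  n <- length(is_true)
  switch(source,
    miranda = stats::rnorm(n, mean = 15 + 10 * info * is_true, sd = 2),
    pictar = ifelse(
      is_true,
      1000 * stats::rbeta(n, 1 + 9 * info, 1),
      stats::runif(n, 0, 1000)
    ),
    targetscan = ifelse(
      is_true,
      stats::rbeta(n, 1 + 9 * info, 3 - 2 * info),
      stats::rbeta(n, 1, 3)
    ),
    stop("unknown source '", source, "'", call. = FALSE)
  )
}

#' Generate per-source target-site prediction tables
#'
#' Each source emits sites for a truth-enriched subset of pairs (true
#' pairs are detected with `detect_prob_true`, false pairs with
#' `detect_prob_false`) and draws scores from its native range, shifted
#' for true pairs according to the source's informativeness: miRanda
#' scores are Normal(15, 2) with a shift of up to +10; PicTar scores are
#' Uniform(0, 1000) for false pairs and Beta-skewed toward 1000 for true
#' pairs; TargetScan P_CT values are Beta(1, 3) for false pairs and
#' shifted toward 1 for true pairs.  Site ids are shared across sources,
#' so a site detected by several sources yields one multi-feature row
#' after assembly.
#'
#' @param truth a `simulation_truth`.
#' @return a named list of prediction data frames (columns `mirna_id`,
#'   `gene_id`, `site_id`, `source`, `score`), one per source.
#' @export
generate_prediction_tables <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  pairs <- truth$pairs
  n <- nrow(pairs)
  site_ids <- lapply(seq_len(n), function(i) {
    sprintf("s%d.%d", i, seq_len(pairs$n_sites[i]))
  })
  with_seed(truth$seed + 2L, {
    out <- lapply(names(truth$informativeness), function(src) {
      p_detect <- ifelse(
        pairs$is_true, truth$detect_prob_true, truth$detect_prob_false
      )
      detected <- stats::runif(n) < p_detect
      idx <- rep(which(detected), pairs$n_sites[detected])
      sites <- unlist(site_ids[detected], use.names = FALSE)
      data.frame(
        mirna_id = pairs$mirna_id[idx],
        gene_id = pairs$gene_id[idx],
        site_id = sites,
        source = rep(src, length(idx)),
        score = draw_source_scores(
          src, pairs$is_true[idx], truth$informativeness[[src]]
        ),
        stringsAsFactors = FALSE
      )
    })
    stats::setNames(out, names(truth$informativeness))
  })
}

#' Generate a partially covering, contaminated gold standard
#'
#' Emulates a curated validation database: only a fraction of the true
#' pairs are covered, a small fraction of non-regulatory pairs leak in,
#' and a configurable share of entries is tagged as high-throughput
#' evidence.
#'
#' @param truth a `simulation_truth`.
#' @param coverage fraction of true pairs included (default 0.8).
#' @param contamination fraction of false pairs included (default 0.01).
#' @param high_throughput_fraction expected fraction of entries tagged
#'   `high_throughput` rather than `individual` (default 0.25).
#' @return a gold-standard data frame (columns `mirna_id`, `gene_id`,
#'   `experiment_type`, `provenance`) in the layout of
#'   [read_gold_standard()].
#' @export
generate_gold_standard <- function(truth, coverage = 0.8,
                                   contamination = 0.01,
                                   high_throughput_fraction = 0.25) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (any(c(coverage, contamination, high_throughput_fraction) < 0) ||
    any(c(coverage, contamination, high_throughput_fraction) > 1)) {
    stop("coverage, contamination and high_throughput_fraction must lie ",
      "in [0, 1]",
      call. = FALSE
    )
  }
  pairs <- truth$pairs
  with_seed(truth$seed + 3L, {
    true_idx <- which(pairs$is_true)
    false_idx <- which(!pairs$is_true)
    take_true <- if (length(true_idx)) {
      sample(true_idx, round(coverage * length(true_idx)))
    } else {
      integer(0)
    }
    take_false <- if (length(false_idx)) {
      sample(false_idx, round(contamination * length(false_idx)))
    } else {
      integer(0)
    }
    idx <- sort(c(take_true, take_false))
    n <- length(idx)
    data.frame(
      mirna_id = pairs$mirna_id[idx],
      gene_id = pairs$gene_id[idx],
      experiment_type = ifelse(
        stats::runif(n) < high_throughput_fraction,
        "high_throughput", "individual"
      ),
      provenance = rep("synthetic", n),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a full synthetic dataset
#'
#' Convenience wrapper producing all artifacts of one simulated study.
#'
#' @param truth a `simulation_truth`.
#' @param n_samples,noise_sd passed to [generate_expression()].
#' @param coverage,contamination,high_throughput_fraction passed to
#'   [generate_gold_standard()].
#' @return a list with `truth`, `mirna_expr`, `gene_expr`, `predictions`
#'   (named list of per-source tables), `gold`.
#' @export
simulate_dataset <- function(truth, n_samples = 58L, noise_sd = 1.0,
                             coverage = 0.8, contamination = 0.01,
                             high_throughput_fraction = 0.25) {
  expr <- generate_expression(truth, n_samples = n_samples, noise_sd = noise_sd)
  list(
    truth = truth,
    mirna_expr = expr$mirna,
    gene_expr = expr$gene,
    predictions = generate_prediction_tables(truth),
    gold = generate_gold_standard(
      truth,
      coverage = coverage, contamination = contamination,
      high_throughput_fraction = high_throughput_fraction
    )
  )
}

#' Simulate a feature table directly from known coefficients
#'
#' Draws feature vectors from the source-native marginal distributions
#' (miRanda ~ Normal(15, 2); PicTar normalized ~ Uniform(0, 1);
#' TargetScan P_CT ~ Beta(1, 3); expression score ~ an equal mixture of
#' the point mass at 1 and Uniform(0, 1), mimicking the positive-slope
#' gate) and labels each row Bernoulli(sigmoid(b0 + sum b_k x_k)).  Useful
#' for parameter-recovery checks of [fit_model()] against a known
#' generating model.
#'
#' @param n number of rows (sites).
#' @param beta numeric vector of length 5: intercept, then coefficients
#'   for `x_miranda`, `x_pictar`, `x_targetscan`, `x_expr`.
#' @param seed integer seed.
#' @return a `feature_table` data frame.
#' @export
simulate_feature_table <- function(n, beta, seed = 1L) {
  if (length(beta) != 5L) {
    stop("beta must be intercept + 4 feature coefficients", call. = FALSE)
  }
  with_seed(seed, {
    x <- cbind(
      x_miranda = stats::rnorm(n, 15, 2),
      x_pictar = stats::runif(n),
      x_targetscan = stats::rbeta(n, 1, 3),
      x_expr = ifelse(stats::runif(n) < 0.5, 1, stats::runif(n))
    )
    p <- stats::plogis(drop(beta[1L] + x %*% beta[-1L]))
    out <- data.frame(
      mirna_id = sprintf("hsa-miR-%d", 100L + (seq_len(n) %% 50L)),
      gene_id = sprintf("GENE%05d", seq_len(n)),
      site_id = rep("s1", n),
      x,
      label = as.integer(stats::runif(n) < p),
      imputed_flags = rep("", n),
      stringsAsFactors = FALSE
    )
    class(out) <- c("feature_table", class(out))
    out
  })
}
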