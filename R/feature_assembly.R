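# Feature assembly.
#
# Joins the per-source site predictions into one feature vector per target
# site, attaches the gene-level expression score, normalizes PicTar scores
# to [0, 1], and labels each row by membership of its (miRNA, gene) pair in
# the active gold standard.  Labels live at the pair level because curated
# validation records pairs, while predictions are site-level.

FEATURE_NAMES <- c("x_miranda", "x_pictar", "x_targetscan", "x_expr")

# Neutral fill per feature, i.e. the least favorable value given each
# feature's orientation (high score = support for the three algorithms,
# low p-value = support for expression).
NEUTRAL_FILLS <- c(x_miranda = 0, x_pictar = 0, x_targetscan = 0, x_expr = 1)

#' Normalize PicTar scores to \[0, 1\]
#'
#' PicTar scores have a maximum of 1000; they are normalized by dividing by
#' that maximum.  Values outside \[0, 1000\] indicate corrupt input and are
#' rejected.  `NA`s pass through (handled by the missing-data policy).
#'
#' @param raw numeric vector of raw PicTar scores.
#' @return numeric vector in \[0, 1\].
#' @examples
#' normalize_pictar(c(0, 500, 1000))
#' @export
normalize_pictar <- function(raw) {
  if (any(raw < 0, na.rm = TRUE)) {
    stop("PicTar scores must be non-negative", call. = FALSE)
  }
  if (any(raw > 1000, na.rm = TRUE)) {
    stop("PicTar score exceeds the maximum of 1000 (corrupt input)",
      call. = FALSE
    )
  }
  raw / 1000
}

#' Build a gold standard variant
#'
#' Constructs the positive-pair set against which feature rows are
#' labelled.  Three variants are supported: the curated set as-is
#' (`"tarbase"`), the curated set restricted to pairs not solely supported
#' by high-throughput assays (`"tarbase_no_highthroughput"`), and the union
#' of the curated set with expression-corroborated pairs whose expression
#' score falls below a threshold (`"tarbase_plus_lcl"`).
#'
#' @param entries data frame of curated pairs from [read_gold_standard()].
#' @param variant one of `"tarbase"`, `"tarbase_plus_lcl"`,
#'   `"tarbase_no_highthroughput"`.
#' @param associations expression associations from [associate_pairs()];
#'   required for `"tarbase_plus_lcl"`.
#' @param lcl_p_threshold expression-score threshold in (0, 1) below which
#'   a pair counts as expression-corroborated (default 0.01).
#' @return a `gold_standard` object: list with `variant`, `pairs` (data
#'   frame of `mirna_id`, `gene_id`), `lcl_p_threshold`.
#' @export
build_gold_standard <- function(entries,
                                variant = c(
                                  "tarbase", "tarbase_plus_lcl",
                                  "tarbase_no_highthroughput"
                                ),
                                associations = NULL,
                                lcl_p_threshold = 0.01) {
  variant <- match.arg(variant)
  base_pairs <- unique(entries[, c("mirna_id", "gene_id")])
  pairs <- switch(variant,
    tarbase = base_pairs,
    tarbase_no_highthroughput = {
      keep <- entries$experiment_type != "high_throughput"
      unique(entries[keep, c("mirna_id", "gene_id")])
    },
    tarbase_plus_lcl = {
      if (is.null(associations)) {
        stop("variant 'tarbase_plus_lcl' requires expression associations",
          call. = FALSE
        )
      }
      if (!(lcl_p_threshold > 0 && lcl_p_threshold < 1)) {
        stop("lcl_p_threshold must lie in (0, 1)", call. = FALSE)
      }
      corroborated <- associations[
        associations$expr_score < lcl_p_threshold,
        c("mirna_id", "gene_id")
      ]
      unique(rbind(base_pairs, corroborated))
    }
  )
  pairs <- pairs[order(pairs$mirna_id, pairs$gene_id), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(
    list(
      variant = variant,
      pairs = pairs,
      lcl_p_threshold = if (variant == "tarbase_plus_lcl") {
        lcl_p_threshold
      } else {
        NA_real_
      }
    ),
    class = "gold_standard"
  )
}

as_gold_standard <- function(gold) {
  if (inherits(gold, "gold_standard")) {
    return(gold)
  }
  if (is.data.frame(gold)) {
    return(build_gold_standard(gold, "tarbase"))
  }
  stop("gold must be a gold_standard object or a data frame of entries",
    call. = FALSE
  )
}

#' Assemble the per-site feature table
#'
#' Builds one row per target site over the union of sites across the
#' prediction sources, with columns `x_miranda` (native alignment-score
#' scale), `x_pictar` (normalized to \[0, 1\]), `x_targetscan` (conserved
#' targeting probability in \[0, 1\]) and `x_expr` (expression score in
#' \[0, 1\], joined at the (miRNA, gene) level so all sites of a pair share
#' it).  `label` is 1 iff the row's pair is in the gold standard.
#'
#' @param predictions a data frame of predictions carrying a `source`
#'   column, or a list of such data frames (e.g. one per
#'   [read_prediction_table()] call).  Allowed sources: `miranda`,
#'   `pictar`, `targetscan`.
#' @param associations expression associations from [associate_pairs()],
#'   or `NULL` if no expression data is available.
#' @param gold a `gold_standard` object (or a data frame of curated
#'   entries, used as-is).
#' @param missing_policy `"impute_neutral"` (default) fills a missing
#'   feature with its least favorable value (`x_miranda`, `x_pictar`,
#'   `x_targetscan` -> 0; `x_expr` -> 1) and records the fills in
#'   `imputed_flags`; `"complete_cases"` drops rows missing any feature.
#' @return a `feature_table` data frame with columns `mirna_id`,
#'   `gene_id`, `site_id`, the four features, `label` (integer 0/1) and
#'   `imputed_flags` (comma-joined imputed feature names), sorted on the
#'   site key.
#' @seealso [fit_model()], [write_feature_table()]
#' @export
assemble_features <- function(predictions, associations, gold,
                              missing_policy = c(
                                "impute_neutral", "complete_cases"
                              )) {
  missing_policy <- match.arg(missing_policy)
  gold <- as_gold_standard(gold)
  if (is.data.frame(predictions)) {
    preds <- predictions
  } else {
    preds <- do.call(rbind, lapply(unname(predictions), as.data.frame))
  }
  if (nrow(preds) == 0L) {
    stop("empty row universe: no predictions supplied", call. = FALSE)
  }
  if (any(preds$source == "expression")) {
    stop(
      "expression scores enter via 'associations', not a prediction table",
      call. = FALSE
    )
  }
  bad <- setdiff(unique(preds$source), c("miranda", "pictar", "targetscan"))
  if (length(bad)) {
    stop("unknown prediction source(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }

  key <- site_key(preds$mirna_id, preds$gene_id, preds$site_id)
  if (anyDuplicated(paste(key, preds$source))) {
    stop("duplicate (site, source) prediction rows", call. = FALSE)
  }
  universe <- !duplicated(key)
  out <- data.frame(
    mirna_id = preds$mirna_id[universe],
    gene_id = preds$gene_id[universe],
    site_id = preds$site_id[universe],
    stringsAsFactors = FALSE
  )
  ukey <- key[universe]

  source_score <- function(src) {
    sub <- preds[preds$source == src, , drop = FALSE]
    sub$score[match(ukey, site_key(sub$mirna_id, sub$gene_id, sub$site_id))]
  }
  out$x_miranda <- source_score("miranda")
  out$x_pictar <- normalize_pictar(source_score("pictar"))
  out$x_targetscan <- source_score("targetscan")
  if (any(out$x_targetscan < 0 | out$x_targetscan > 1, na.rm = TRUE)) {
    stop("TargetScan P_CT scores must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(associations) || nrow(associations) == 0L) {
    out$x_expr <- NA_real_
  } else {
    hit <- match(
      pair_key(out$mirna_id, out$gene_id),
      pair_key(associations$mirna_id, associations$gene_id)
    )
    out$x_expr <- associations$expr_score[hit]
  }

  out$label <- as.integer(
    pair_key(out$mirna_id, out$gene_id) %in%
      pair_key(gold$pairs$mirna_id, gold$pairs$gene_id)
  )

  feat <- as.matrix(out[, FEATURE_NAMES])
  if (missing_policy == "complete_cases") {
    keep <- rowSums(is.na(feat)) == 0L
    out <- out[keep, , drop = FALSE]
    out$imputed_flags <- rep("", nrow(out))
  } else {
    miss <- is.na(feat)
    for (f in FEATURE_NAMES) {
      out[[f]][is.na(out[[f]])] <- NEUTRAL_FILLS[[f]]
    }
    out$imputed_flags <- apply(miss, 1L, function(m) {
      paste(FEATURE_NAMES[m], collapse = ",")
    })
  }

  out <- out[order(out$mirna_id, out$gene_id, out$site_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("feature_table", class(out))
  out
}

#' Pairwise correlation of two sources' scores
#'
#' Correlates the scores of two prediction sources over their shared
#' (miRNA, gene) pairs.  The join is site-agnostic: when a source has
#' multiple sites for a pair, its best (maximum) score per pair is used.
#'
#' @param preds_a,preds_b prediction data frames (see
#'   [read_prediction_table()]).
#' @return a list with `n_overlap`, `pearson_r`, `spearman_rho`.
#' @details Fewer than 3 overlapping pairs is an "insufficient overlap"
#'   error.
#' @export
pairwise_score_correlation <- function(preds_a, preds_b) {
  best <- function(p) {
    k <- pair_key(p$mirna_id, p$gene_id)
    tapply(p$score, k, max)
  }
  a <- best(preds_a)
  b <- best(preds_b)
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3L) {
    stop("insufficient overlap: ", length(shared),
      " shared (mirna, gene) pair(s), need at least 3",
      call. = FALSE
    )
  }
  list(
    n_overlap = length(shared),
    pearson_r = stats::cor(a[shared], b[shared], method = "pearson"),
    spearman_rho = stats::cor(a[shared], b[shared], method = "spearman")
  )
}

#' Compare score distributions of all predictions vs a gold subset
#'
#' Bins the pooled score range into `n_bins` equal-width bins and returns,
#' for each bin, the proportion of all scores and the proportion of
#' gold-standard-supported scores falling in it (each histogram sums
#' to 1).  This is the standard side-by-side view of where experimentally
#' supported targets sit within a source's overall score distribution.
#'
#' @param all_scores numeric vector of scores for the full prediction set.
#' @param gold_subset_scores numeric vector of scores for the
#'   experimentally supported subset.
#' @param n_bins number of equal-width bins (>= 2).
#' @return a data frame with columns `bin_low`, `bin_high`, `prop_all`,
#'   `prop_gold`.
#' @export
binned_distribution_comparison <- function(all_scores, gold_subset_scores,
                                           n_bins = 10L) {
  if (length(gold_subset_scores) == 0L) {
    stop("empty gold subset", call. = FALSE)
  }
  if (n_bins < 2L) {
    stop("n_bins must be at least 2", call. = FALSE)
  }
  pooled <- c(all_scores, gold_subset_scores)
  if (any(!is.finite(pooled))) {
    stop("scores must be finite", call. = FALSE)
  }
  rng <- range(pooled)
  if (rng[1L] == rng[2L]) {
    rng <- rng + c(-0.5, 0.5) # degenerate range: one bin catches all
  }
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  prop <- function(x) {
    counts <- tabulate(
      cut(x, breaks, include.lowest = TRUE, labels = FALSE),
      nbins = n_bins
    )
    counts / length(x)
  }
  data.frame(
    bin_low = breaks[-(n_bins + 1L)],
    bin_high = breaks[-1L],
    prop_all = prop(all_scores),
    prop_gold = prop(gold_subset_scores)
  )
}
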