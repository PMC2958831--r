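# End-to-end pipeline.
#
# associate -> assemble -> fit -> predict -> evaluate -> cross-validate,
# with every output carrying a provenance header (package version, config
# hash, seed, stage) so a rerun with an identical config reproduces the
# output files byte-for-byte.

# Orientation of each feature when evaluated as a lone classifier:
# p-value-like scores support the positive class when *low*.
FEATURE_ORIENTATIONS <- c(
  x_miranda = "higher_is_positive",
  x_pictar = "higher_is_positive",
  x_targetscan = "higher_is_positive",
  x_expr = "lower_is_positive"
)

#' Validate a pipeline configuration
#'
#' Collects and validates everything [run_pipeline()] needs.  All
#' referenced input paths must exist at validation time; nothing is read
#' yet.
#'
#' @param mirna_expr,gene_expr paths to expression-matrix TSVs.
#' @param predictions named character vector of prediction-table paths;
#'   names are source tags (`miranda`, `pictar`, `targetscan`).
#' @param gold path to the curated gold-standard TSV.
#' @param gold_variant,lcl_p_threshold see [build_gold_standard()].
#' @param missing_policy see [assemble_features()].
#' @param features feature subset for the integrative model.
#' @param k_folds number of cross-validation folds.
#' @param seed integer seed (cross-validation partition).
#' @param out_dir output directory (created by [run_pipeline()] if
#'   absent).
#' @return a `run_config` object.
#' @export
run_config <- function(mirna_expr, gene_expr, predictions, gold,
                       gold_variant = c(
                         "tarbase", "tarbase_plus_lcl",
                         "tarbase_no_highthroughput"
                       ),
                       lcl_p_threshold = 0.01,
                       missing_policy = c("impute_neutral", "complete_cases"),
                       features = FEATURE_NAMES,
                       k_folds = 10L, seed = 1L, out_dir = "mirfuse_out") {
  gold_variant <- match.arg(gold_variant)
  missing_policy <- match.arg(missing_policy)
  if (is.null(names(predictions)) || any(!nzchar(names(predictions)))) {
    stop("predictions must be a named vector: source = path", call. = FALSE)
  }
  bad_src <- setdiff(names(predictions), c("miranda", "pictar", "targetscan"))
  if (length(bad_src)) {
    stop("unknown prediction source(s): ", paste(bad_src, collapse = ", "),
      call. = FALSE
    )
  }
  bad_feat <- setdiff(features, FEATURE_NAMES)
  if (length(bad_feat)) {
    stop("unknown feature(s): ", paste(bad_feat, collapse = ", "),
      call. = FALSE
    )
  }
  paths <- c(mirna_expr, gene_expr, unname(predictions), gold)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      mirna_expr = mirna_expr,
      gene_expr = gene_expr,
      predictions = predictions,
      gold = gold,
      gold_variant = gold_variant,
      lcl_p_threshold = lcl_p_threshold,
      missing_policy = missing_policy,
      features = features,
      k_folds = as.integer(k_folds),
      seed = as.integer(seed),
      out_dir = out_dir
    ),
    class = "run_config"
  )
}

stage_call <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(stage, ": ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full integration pipeline
#'
#' Executes, in order: expression association over the union of pairs
#' appearing in any prediction table; gold-standard construction; feature
#' assembly; model fitting; scoring of every assembled site; ROC/AUC
#' evaluation of the integrated score and of each feature as a lone
#' classifier (with the correlated-AUC z test of the integrated score
#' against each single feature); and K-fold cross-validation.  Each stage
#' writes a TSV (or key-value file for the model) into `config$out_dir`
#' with a provenance header.
#'
#' @param config a `run_config`.
#' @return invisibly, a list with the in-memory stage results:
#'   `associations`, `gold`, `features`, `fit`, `predictions`,
#'   `evaluation`, `comparisons`, `cv`, and `paths` (the written files).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  # hash the analytic parameters only, not the output location
  cfg <- unclass(config)
  hash <- content_hash(cfg[setdiff(names(cfg), "out_dir")])
  header <- function(stage) {
    c(
      paste0("generated_by: mirfuse ", as.character(utils::packageVersion("mirfuse"))),
      paste0("config_hash: ", hash),
      paste0("seed: ", config$seed),
      paste0("stage: ", stage)
    )
  }
  out_path <- function(name) file.path(config$out_dir, name)
  paths <- list()

  mirna_mat <- stage_call("read", read_expression_matrix(config$mirna_expr))
  gene_mat <- stage_call("read", read_expression_matrix(config$gene_expr))
  preds <- stage_call("read", lapply(
    stats::setNames(nm = names(config$predictions)),
    function(src) read_prediction_table(config$predictions[[src]], src)
  ))
  gold_entries <- stage_call("read", read_gold_standard(config$gold))

  associations <- stage_call("associate", {
    all_preds <- do.call(rbind, unname(preds))
    pairs <- unique(all_preds[, c("mirna_id", "gene_id")])
    pairs <- pairs[
      pairs$mirna_id %in% rownames(mirna_mat) &
        pairs$gene_id %in% rownames(gene_mat), ,
      drop = FALSE
    ]
    associate_pairs(mirna_mat, gene_mat, pairs)
  })
  paths$associations <- out_path("associations.tsv")
  write_tsv_body(
    data.frame(
      mirna_id = associations$mirna_id,
      gene_id = associations$gene_id,
      n_samples = associations$n_samples,
      slope = fmt_num(associations$slope),
      p_value = fmt_num(associations$p_value),
      expr_score = fmt_num(associations$expr_score),
      stringsAsFactors = FALSE
    ),
    paths$associations, header("associate")
  )

  gold <- stage_call("assemble", build_gold_standard(
    gold_entries, config$gold_variant,
    associations = associations,
    lcl_p_threshold = config$lcl_p_threshold
  ))
  features <- stage_call("assemble", assemble_features(
    preds, associations, gold,
    missing_policy = config$missing_policy
  ))
  paths$features <- out_path("features.tsv")
  write_feature_table(features, paths$features, header("assemble"))

  fit <- stage_call("fit", fit_model(features, feature_subset = config$features))
  paths$model <- out_path("model.txt")
  write_model_fit(fit, paths$model, header("fit"))

  scores <- stage_call("predict", predict_score(fit, features))
  predictions <- data.frame(
    mirna_id = features$mirna_id,
    gene_id = features$gene_id,
    site_id = features$site_id,
    p = scores,
    stringsAsFactors = FALSE
  )
  paths$predictions <- out_path("predictions.tsv")
  write_tsv_body(
    data.frame(
      predictions[, c("mirna_id", "gene_id", "site_id")],
      p = fmt_num(predictions$p),
      stringsAsFactors = FALSE
    ),
    paths$predictions, header("predict")
  )

  evaluation <- stage_call("evaluate", {
    classifiers <- c(
      list(integrated = list(
        scores = scores, orientation = "higher_is_positive"
      )),
      stats::setNames(
        lapply(config$features, function(f) {
          list(scores = features[[f]], orientation = FEATURE_ORIENTATIONS[[f]])
        }),
        config$features
      )
    )
    ests <- lapply(classifiers, function(cl) {
      auc_estimate(cl$scores, features$label, cl$orientation)
    })
    list(classifiers = classifiers, estimates = ests)
  })
  eval_df <- data.frame(
    classifier = names(evaluation$estimates),
    omega = fmt_num(vapply(evaluation$estimates, `[[`, 0, "omega")),
    se = fmt_num(vapply(evaluation$estimates, `[[`, 0, "se")),
    n_pos = vapply(evaluation$estimates, `[[`, 0, "n_pos"),
    n_neg = vapply(evaluation$estimates, `[[`, 0, "n_neg"),
    stringsAsFactors = FALSE
  )
  paths$evaluation <- out_path("evaluation.tsv")
  write_tsv_body(eval_df, paths$evaluation, header("evaluate"))

  comparisons <- stage_call("evaluate", {
    lapply(config$features, function(f) {
      cl <- evaluation$classifiers[[f]]
      # orient the single-feature scores so both vectors agree in direction
      s_feat <- if (cl$orientation == "lower_is_positive") {
        -cl$scores
      } else {
        cl$scores
      }
      res <- tryCatch(
        {
          r <- estimate_r(scores, s_feat, features$label)
          cmp <- compare_auc(
            evaluation$estimates$integrated, evaluation$estimates[[f]], r
          )
          list(r = r, z = cmp$z, p = cmp$p_two_sided)
        },
        error = function(e) list(r = NA_real_, z = NA_real_, p = NA_real_)
      )
      c(list(classifier_a = "integrated", classifier_b = f), res)
    })
  })
  cmp_df <- data.frame(
    classifier_a = vapply(comparisons, `[[`, "", "classifier_a"),
    classifier_b = vapply(comparisons, `[[`, "", "classifier_b"),
    r = fmt_num(vapply(comparisons, `[[`, 0, "r")),
    z = fmt_num(vapply(comparisons, `[[`, 0, "z")),
    p_two_sided = fmt_num(vapply(comparisons, `[[`, 0, "p")),
    stringsAsFactors = FALSE
  )
  paths$comparison <- out_path("comparison.tsv")
  write_tsv_body(cmp_df, paths$comparison, header("evaluate"))

  cv <- stage_call("cv", kfold_cv(
    features,
    feature_subset = config$features,
    K = config$k_folds, seed = config$seed
  ))
  paths$cv <- out_path("cv.tsv")
  write_tsv_body(
    data.frame(
      K = cv$K,
      seed = cv$seed,
      cost = cv$cost,
      mean_prediction_error = fmt_num(cv$mean_prediction_error),
      fold_sizes = paste(cv$fold_sizes, collapse = ","),
      stringsAsFactors = FALSE
    ),
    paths$cv, header("cv")
  )

  invisible(list(
    associations = associations,
    gold = gold,
    features = features,
    fit = fit,
    predictions = predictions,
    evaluation = evaluation$estimates,
    comparisons = comparisons,
    cv = cv,
    paths = paths
  ))
}
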