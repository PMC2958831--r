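# Tabular input/output.
#
# One TSV dialect for everything: UTF-8, tab-separated, '#' comment lines
# ignored, blank lines ignored, header row mandatory.  Identifiers are
# matched by exact string equality after trimming and miRNA-name case
# normalization; no alias resolution is attempted.

VALID_SOURCES <- c("miranda", "pictar", "targetscan", "expression")
VALID_EXPERIMENT_TYPES <- c("individual", "high_throughput", "expression_lcl")

# Split TSV lines preserving trailing empty fields; returns header, data
# rows and the original 1-based line number of every data row (for error
# messages).
read_tsv_rows <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: '", path, "'", call. = FALSE)
  }
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^[[:space:]]*#", raw) & nzchar(trimws(raw))
  lineno <- which(keep)
  lines <- raw[keep]
  if (length(lines) == 0L) {
    stop("no header row found in '", path, "'", call. = FALSE)
  }
  fields <- strsplit(paste0(lines, "\t\035"), "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) f[-length(f)])
  list(
    header = trimws(fields[[1L]]),
    rows = fields[-1L],
    lineno = lineno[-1L],
    path = path
  )
}

# Validate row widths and return a character matrix (rows x header).
tsv_as_matrix <- function(tb) {
  ncol <- length(tb$header)
  widths <- lengths(tb$rows)
  if (any(widths != ncol)) {
    bad <- which(widths != ncol)[1L]
    stop(
      "ragged row in '", tb$path, "' at line ", tb$lineno[bad],
      ": expected ", ncol, " fields, found ", widths[bad],
      call. = FALSE
    )
  }
  m <- matrix(
    c(character(0), unlist(tb$rows, use.names = FALSE)),
    nrow = length(tb$rows), ncol = ncol, byrow = TRUE
  )
  colnames(m) <- tb$header
  m
}

require_columns <- function(tb, need) {
  missing <- setdiff(need, tb$header)
  if (length(missing) > 0L) {
    stop(
      "'", tb$path, "' is missing required column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
}

parse_numeric_column <- function(x, lineno, column, path) {
  val <- suppressWarnings(as.numeric(trimws(x)))
  bad <- !is.finite(val)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(
      "non-numeric ", column, " '", x[i], "' in '", path,
      "' at line ", lineno[i],
      call. = FALSE
    )
  }
  val
}

#' Normalize a miRNA identifier
#'
#' Trims whitespace and lower-cases the name while restoring the canonical
#' mixed case of the `miR` token, so that e.g. `"HSA-MIR-138 "` becomes
#' `"hsa-miR-138"`.  `let`-family names are already lower case.
#'
#' @param x character vector of miRNA names.
#' @return character vector of normalized names.
#' @examples
#' normalize_mirna_id(c("HSA-MIR-138", " hsa-let-7a"))
#' @export
normalize_mirna_id <- function(x) {
  x <- tolower(trimws(x))
  gsub("(^|-)mir(?=-|$)", "\\1miR", x, perl = TRUE)
}

#' Read a target-site prediction table
#'
#' Reads a TSV of per-site predictions from one source algorithm.  Required
#' columns: `mirna_id`, `gene_id`, `site_id`, `score`.  The source tag is
#' stamped on every record and miRNA names are case-normalized with
#' [normalize_mirna_id()].
#'
#' @param path path to a TSV file ('#' comment lines ignored).
#' @param source one of `"miranda"`, `"pictar"`, `"targetscan"`,
#'   `"expression"`; the algorithm the scores come from.
#' @return a data frame with columns `mirna_id`, `gene_id`, `site_id`,
#'   `source`, `score`, one row per prediction.
#' @details A repeated `(mirna_id, gene_id, site_id)` key or a non-numeric
#'   score is a hard error naming the offending line.  A header-only file
#'   yields an empty table.
#' @seealso [write_prediction_table()], [assemble_features()]
#' @export
read_prediction_table <- function(path, source = VALID_SOURCES) {
  source <- match.arg(source)
  tb <- read_tsv_rows(path)
  require_columns(tb, c("mirna_id", "gene_id", "site_id", "score"))
  m <- tsv_as_matrix(tb)
  out <- data.frame(
    mirna_id = normalize_mirna_id(m[, "mirna_id"]),
    gene_id = trimws(m[, "gene_id"]),
    site_id = trimws(m[, "site_id"]),
    source = rep(source, nrow(m)),
    score = if (nrow(m)) {
      parse_numeric_column(m[, "score"], tb$lineno, "score", path)
    } else {
      numeric(0)
    },
    stringsAsFactors = FALSE
  )
  key <- site_key(out$mirna_id, out$gene_id, out$site_id)
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop(
      "duplicate (mirna_id, gene_id, site_id) key '",
      paste(out$mirna_id[i], out$gene_id[i], out$site_id[i], sep = ", "),
      "' in '", path, "' at line ", tb$lineno[i],
      call. = FALSE
    )
  }
  out
}

#' Write a target-site prediction table
#'
#' @param predictions data frame as returned by [read_prediction_table()].
#' @param path output path.
#' @param comments optional character vector written as leading '#' lines.
#' @return `path`, invisibly.
#' @export
write_prediction_table <- function(predictions, path, comments = NULL) {
  write_tsv_body(
    data.frame(
      mirna_id = predictions$mirna_id,
      gene_id = predictions$gene_id,
      site_id = predictions$site_id,
      score = fmt_num(predictions$score),
      stringsAsFactors = FALSE
    ),
    path, comments
  )
}

#' Read an expression matrix
#'
#' Reads a TSV whose first header cell is literally `entity_id`, the
#' remaining header cells being sample identifiers; one row per miRNA or
#' gene/transcript, values are log2-scale expression intensities.
#'
#' @param path path to a TSV file.
#' @return a numeric matrix, entities in rows (rownames = entity ids),
#'   samples in columns (colnames = sample ids), in file order.
#' @details Ragged rows, duplicate entity or sample ids, and empty or
#'   non-numeric cells are hard errors: missing values are rejected at
#'   load.
#' @seealso [write_expression_matrix()], [associate_pairs()]
#' @export
read_expression_matrix <- function(path) {
  tb <- read_tsv_rows(path)
  if (tb$header[1L] != "entity_id") {
    stop(
      "first header cell of '", path, "' must be 'entity_id', found '",
      tb$header[1L], "'",
      call. = FALSE
    )
  }
  m <- tsv_as_matrix(tb)
  sample_ids <- tb$header[-1L]
  if (length(sample_ids) == 0L) {
    stop("'", path, "' has no sample columns", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop(
      "duplicate sample id '", sample_ids[duplicated(sample_ids)][1L],
      "' in '", path, "'",
      call. = FALSE
    )
  }
  entity_ids <- trimws(m[, 1L, drop = TRUE])
  if (anyDuplicated(entity_ids)) {
    i <- which(duplicated(entity_ids))[1L]
    stop(
      "duplicate entity id '", entity_ids[i], "' in '", path,
      "' at line ", tb$lineno[i],
      call. = FALSE
    )
  }
  cells <- m[, -1L, drop = FALSE]
  empty <- array(!nzchar(trimws(cells)), dim = dim(cells))
  if (any(empty)) {
    i <- which(empty, arr.ind = TRUE)[1L, ]
    stop(
      "empty cell in '", path, "' at line ", tb$lineno[i[["row"]]],
      ", column '", sample_ids[i[["col"]]], "'",
      call. = FALSE
    )
  }
  values <- suppressWarnings(as.numeric(cells))
  if (any(!is.finite(values))) {
    i <- which(!is.finite(values), arr.ind = FALSE)[1L]
    row <- ((i - 1L) %% nrow(cells)) + 1L
    stop(
      "non-numeric expression value '", cells[i], "' in '", path,
      "' at line ", tb$lineno[row],
      call. = FALSE
    )
  }
  out <- matrix(values, nrow = nrow(cells), ncol = ncol(cells))
  rownames(out) <- entity_ids
  colnames(out) <- sample_ids
  out
}

#' Write an expression matrix
#'
#' @param mat numeric matrix with entity rownames and sample colnames.
#' @param path output path.
#' @param comments optional character vector written as leading '#' lines.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path, comments = NULL) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  body <- cbind(
    entity_id = rownames(mat),
    matrix(fmt_num(mat), nrow = nrow(mat), dimnames = list(NULL, colnames(mat)))
  )
  write_tsv_body(as.data.frame(body, stringsAsFactors = FALSE), path, comments)
}

#' Read a gold standard of experimentally supported miRNA-gene pairs
#'
#' Reads a TSV with columns `mirna_id`, `gene_id` and optionally
#' `experiment_type` (defaulting to `"individual"`) and `provenance`.
#' Entries are deduplicated on `(mirna_id, gene_id)`; when duplicates
#' disagree on experiment type, the more specific tag wins
#' (`individual` > `expression_lcl` > `high_throughput`), so a pair
#' validated both individually and by a high-throughput assay survives a
#' later filter that drops high-throughput evidence.
#'
#' @param path path to a TSV file.
#' @return a data frame with columns `mirna_id`, `gene_id`,
#'   `experiment_type`, `provenance`, sorted on `(mirna_id, gene_id)`.
#' @seealso [build_gold_standard()]
#' @export
read_gold_standard <- function(path) {
  tb <- read_tsv_rows(path)
  require_columns(tb, c("mirna_id", "gene_id"))
  m <- tsv_as_matrix(tb)
  n <- nrow(m)
  type <- if ("experiment_type" %in% tb$header) {
    trimws(m[, "experiment_type"])
  } else {
    rep("individual", n)
  }
  bad <- !(type %in% VALID_EXPERIMENT_TYPES)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(
      "unknown experiment_type '", type[i], "' in '", path,
      "' at line ", tb$lineno[i], " (expected one of: ",
      paste(VALID_EXPERIMENT_TYPES, collapse = ", "), ")",
      call. = FALSE
    )
  }
  out <- data.frame(
    mirna_id = normalize_mirna_id(m[, "mirna_id"]),
    gene_id = trimws(m[, "gene_id"]),
    experiment_type = type,
    provenance = if ("provenance" %in% tb$header) {
      trimws(m[, "provenance"])
    } else {
      rep("", n)
    },
    stringsAsFactors = FALSE
  )
  # Deduplicate with experiment-type precedence; canonical pair order.
  rank <- match(out$experiment_type, VALID_EXPERIMENT_TYPES)
  rank[out$experiment_type == "expression_lcl"] <- 2L
  rank[out$experiment_type == "high_throughput"] <- 3L
  ord <- order(out$mirna_id, out$gene_id, rank)
  out <- out[ord, , drop = FALSE]
  out <- out[!duplicated(pair_key(out$mirna_id, out$gene_id)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a gold-standard table
#'
#' @param gold data frame as returned by [read_gold_standard()].
#' @param path output path.
#' @param comments optional character vector written as leading '#' lines.
#' @return `path`, invisibly.
#' @export
write_gold_standard <- function(gold, path, comments = NULL) {
  write_tsv_body(
    gold[, c("mirna_id", "gene_id", "experiment_type", "provenance")],
    path, comments
  )
}

#' Read an assembled feature table
#'
#' @param path path to a TSV written by [write_feature_table()].
#' @return a `feature_table` data frame (see [assemble_features()]).
#' @export
read_feature_table <- function(path) {
  tb <- read_tsv_rows(path)
  need <- c(
    "mirna_id", "gene_id", "site_id",
    "x_miranda", "x_pictar", "x_targetscan", "x_expr",
    "label", "imputed_flags"
  )
  require_columns(tb, need)
  m <- tsv_as_matrix(tb)
  num <- function(col) {
    v <- suppressWarnings(as.numeric(m[, col]))
    v[m[, col] == "NA"] <- NA_real_
    v
  }
  out <- data.frame(
    mirna_id = m[, "mirna_id"],
    gene_id = m[, "gene_id"],
    site_id = m[, "site_id"],
    x_miranda = num("x_miranda"),
    x_pictar = num("x_pictar"),
    x_targetscan = num("x_targetscan"),
    x_expr = num("x_expr"),
    label = as.integer(m[, "label"]),
    imputed_flags = m[, "imputed_flags"],
    stringsAsFactors = FALSE
  )
  class(out) <- c("feature_table", class(out))
  out
}

#' Write an assembled feature table
#'
#' @param table a `feature_table` from [assemble_features()].
#' @param path output path.
#' @param comments optional character vector written as leading '#' lines.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, comments = NULL) {
  write_tsv_body(
    data.frame(
      mirna_id = table$mirna_id,
      gene_id = table$gene_id,
      site_id = table$site_id,
      x_miranda = fmt_num(table$x_miranda),
      x_pictar = fmt_num(table$x_pictar),
      x_targetscan = fmt_num(table$x_targetscan),
      x_expr = fmt_num(table$x_expr),
      label = table$label,
      imputed_flags = table$imputed_flags,
      stringsAsFactors = FALSE
    ),
    path, comments
  )
}

# Shared TSV writer: optional '#' comment lines, then header, then body.
write_tsv_body <- function(df, path, comments = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comments) && length(comments) > 0L) {
    writeLines(paste0("# ", comments), con)
  }
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df) > 0L) {
    body <- do.call(paste, c(lapply(df, as.character), list(sep = "\t")))
    writeLines(body, con)
  }
  invisible(path)
}
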