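#' Declare a feature schema
#'
#' A feature schema fixes the set of feature columns a gene feature table must
#' carry and whether each is binary (0/1 flags such as `is_stop_gained`) or
#' numeric (counts and rates such as `normalized_nonsyn_SNP` or
#' `network_weight`). Rankings are only comparable between tables that share a
#' schema, so readers validate against it.
#'
#' @param feature_names Character vector of unique feature (column) names.
#' @param feature_kinds Character vector, one of `"binary"` or `"numeric"` per
#'   feature. Either named by feature or given in the same order as
#'   `feature_names`.
#' @param species_tag Free-text label for the genome the schema describes.
#'
#' @return A `qtg_schema` object (a list with elements `feature_names`,
#'   `feature_kinds`, `species_tag`).
#' @export
#' @examples
#' feature_schema(c("is_transporter", "network_weight"),
#'                c("binary", "numeric"), species_tag = "demo")
feature_schema <- function(feature_names, feature_kinds, species_tag = "") {
  feature_names <- as.character(feature_names)
  if (anyDuplicated(feature_names)) {
    stop("duplicate feature names: ",
         paste(unique(feature_names[duplicated(feature_names)]), collapse = ", "))
  }
  if (is.null(names(feature_kinds))) {
    if (length(feature_kinds) != length(feature_names)) {
      stop("feature_kinds must be named or match feature_names in length")
    }
    names(feature_kinds) <- feature_names
  }
  feature_kinds <- feature_kinds[feature_names]
  if (anyNA(feature_kinds) || !all(feature_kinds %in% c("binary", "numeric"))) {
    stop("every feature needs a kind in {binary, numeric}")
  }
  structure(
    list(feature_names = feature_names,
         feature_kinds = feature_kinds,
         species_tag = as.character(species_tag)[1]),
    class = "qtg_schema"
  )
}

#' @export
print.qtg_schema <- function(x, ...) {
  cat("<qtg_schema> ", length(x$feature_names), " features (",
      sum(x$feature_kinds == "binary"), " binary, ",
      sum(x$feature_kinds == "numeric"), " numeric)",
      if (nzchar(x$species_tag)) paste0(" [", x$species_tag, "]"), "\n", sep = "")
  invisible(x)
}

infer_schema <- function(df, species_tag = "") {
  feats <- setdiff(names(df), "gene_id")
  kinds <- vapply(feats, function(f) {
    v <- df[[f]]
    if (all(v %in% c(0, 1))) "binary" else "numeric"
  }, character(1))
  feature_schema(feats, kinds, species_tag = species_tag)
}

#' Validate a gene feature table
#'
#' Checks a data frame of per-gene features against a schema: unique gene ids,
#' all-finite numeric values, binary columns restricted to {0, 1} and
#' count-derived numeric columns non-negative. When no schema is supplied the
#' kind of each column is inferred (a column containing only 0 and 1 is
#' binary, anything else numeric) and recorded on the returned table.
#'
#' @param df Data frame with a `gene_id` column followed by feature columns.
#' @param schema Optional [feature_schema()]. An explicit schema always wins
#'   over inference and its binary constraint is enforced.
#'
#' @return A tibble of class `qtg_feature_table` with the schema attached as
#'   attribute `"schema"`.
#' @export
as_feature_table <- function(df, schema = NULL) {
  df <- tibble::as_tibble(df)
  if (!"gene_id" %in% names(df)) stop("feature table needs a 'gene_id' column")
  df$gene_id <- as.character(df$gene_id)
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup)) stop("duplicate gene id(s): ", paste(dup, collapse = ", "))

  feats <- setdiff(names(df), "gene_id")
  for (f in feats) {
    v <- df[[f]]
    if (!is.numeric(v)) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric value in column '%s' (row %d)", f,
                   if (is.na(bad)) 1L else bad))
    }
    if (any(!is.finite(v))) {
      stop(sprintf("non-finite value in column '%s' (row %d)", f,
                   which(!is.finite(v))[1]))
    }
  }

  if (is.null(schema)) {
    schema <- infer_schema(df)
  } else {
    if (!inherits(schema, "qtg_schema")) stop("schema must be a qtg_schema")
    missing_cols <- setdiff(schema$feature_names, feats)
    if (length(missing_cols)) {
      stop("feature table lacks schema column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    df <- df[, c("gene_id", schema$feature_names)]
    for (f in schema$feature_names[schema$feature_kinds == "binary"]) {
      if (!all(df[[f]] %in% c(0, 1))) {
        stop(sprintf("binary column '%s' contains values outside {0,1}", f))
      }
    }
  }
  structure(df, schema = schema,
            class = c("qtg_feature_table", class(df)))
}

#' @rdname as_feature_table
#' @param x A feature table.
#' @export
feature_table_schema <- function(x) attr(x, "schema")

#' Read a gene feature table from TSV
#'
#' The file is tab-delimited with a header row; the first column is the gene
#' identifier (renamed to `gene_id` if headed otherwise) and the remaining
#' columns are features. See [as_feature_table()] for validation and kind
#' inference.
#'
#' @param path Path to the TSV file.
#' @param schema Optional [feature_schema()]; inferred when absent.
#' @return A validated `qtg_feature_table` tibble.
#' @export
read_feature_table <- function(path, schema = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 1) stop("empty feature table: ", path)
  names(df)[1] <- "gene_id"
  as_feature_table(df, schema = schema)
}

#' Write a gene feature table to TSV
#'
#' Inverse of [read_feature_table()]: values round-trip exactly for numbers
#' representable in decimal at full double precision.
#'
#' @param x A feature table (tibble with `gene_id` first).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  stopifnot(names(x)[1] == "gene_id")
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}

# Numeric matrix of the feature columns, rownames = gene ids.
feature_matrix <- function(x) {
  feats <- setdiff(names(x), "gene_id")
  m <- as.matrix(as.data.frame(x)[, feats, drop = FALSE])
  rownames(m) <- x$gene_id
  m
}

#' Pairwise Pearson correlation between features
#'
#' Diagnostic for redundancy among features: the classifier tolerates
#' correlated inputs, but leave-one-out importance is masked by near-duplicate
#' columns, so inspecting the correlation structure is part of feature QC.
#' Correlations involving a constant (zero-variance) column are undefined and
#' reported as 0 with a warning.
#'
#' @param table A feature table.
#' @return A symmetric correlation matrix with unit diagonal, dimnames the
#'   feature names.
#' @export
feature_correlation <- function(table) {
  m <- feature_matrix(table)
  if (nrow(m) < 2) stop("need at least 2 genes to correlate features")
  sds <- apply(m, 2, stats::sd)
  cc <- suppressWarnings(stats::cor(m))
  if (any(sds == 0)) {
    warning("constant feature column(s) ",
            paste(colnames(m)[sds == 0], collapse = ", "),
            ": correlations reported as 0")
    cc[is.na(cc)] <- 0
  }
  diag(cc) <- 1
  cc
}
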