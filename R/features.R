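polymorphism_flag_columns <- c(
  nonsynonymous_deleterious = "is_nonsyn_deleterious",
  start_lost = "is_start_lost",
  start_gained = "is_start_gained",
  stop_gained = "is_stop_gained",
  stop_lost = "is_stop_lost",
  splice_site = "is_splice_site",
  cis_element = "is_SNP_cis"
)

#' Polymorphism features from annotated variants
#'
#' Per gene: `normalized_nonsyn_SNP` is the number of distinct variant records
#' tagged nonsynonymous divided by the protein length in amino acids, and each
#' binary flag (`is_nonsyn_deleterious`, `is_start_lost`, `is_start_gained`,
#' `is_stop_gained`, `is_stop_lost`, `is_splice_site`, `is_SNP_cis`) is 1 iff
#' at least one variant in the gene carries the corresponding tag. Genes with
#' no variants get all-zero features. Unique tagged sites are counted, not
#' accession-weighted allele counts.
#'
#' @param variants Tibble of annotated variants (see
#'   [read_annotated_variants()]).
#' @param lengths Protein lengths: a named numeric vector (names = gene ids)
#'   or a data frame with columns `gene_id`, `protein_length`. Required for
#'   every gene that has nonsynonymous variants.
#' @param gene_ids Character vector: the gene universe of the output.
#' @return A feature-table tibble over `gene_ids` with the eight polymorphism
#'   columns.
#' @export
polymorphism_features <- function(variants, lengths, gene_ids) {
  if (is.data.frame(lengths)) {
    lengths <- stats::setNames(lengths$protein_length, lengths$gene_id)
  }
  if (any(lengths < 1, na.rm = TRUE)) stop("protein lengths must be >= 1")
  unknown <- setdiff(variants$gene_id, gene_ids)
  if (length(unknown)) {
    stop("variant(s) assigned to gene(s) outside the universe: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  out <- tibble::tibble(gene_id = as.character(gene_ids))
  # flatten (variant, tag) pairs once; per-tag flags are then simple lookups
  tag_flat <- unlist(variants$effect_tags)
  row_flat <- rep(seq_len(nrow(variants)), lengths(variants$effect_tags))
  has_tag <- function(tag) {
    flagged <- logical(nrow(variants))
    flagged[row_flat[tag_flat == tag]] <- TRUE
    flagged
  }
  nonsyn_counts <- table(variants$gene_id[has_tag("nonsynonymous")])
  counts <- as.numeric(nonsyn_counts[out$gene_id])
  counts[is.na(counts)] <- 0
  need_len <- out$gene_id[counts > 0]
  missing_len <- need_len[is.na(lengths[need_len])]
  if (length(missing_len)) {
    stop("missing protein length for gene(s) with nonsynonymous variants: ",
         paste(utils::head(missing_len, 5), collapse = ", "))
  }
  len <- as.numeric(lengths[out$gene_id])
  out$normalized_nonsyn_SNP <- ifelse(counts > 0, counts / len, 0)
  for (tag in names(polymorphism_flag_columns)) {
    flagged <- unique(variants$gene_id[has_tag(tag)])
    out[[polymorphism_flag_columns[[tag]]]] <- as.numeric(out$gene_id %in% flagged)
  }
  out
}

#' Co-function network weight per gene
#'
#' The sum of edge weights incident to a gene in the co-function network, a
#' proxy for being a functional hub. Duplicate undirected pairs in the edge
#' list are summed first, so the result is invariant to edge order and to
#' splitting an edge's weight over several records.
#'
#' @param edges Edge list (columns `gene_a`, `gene_b`, `weight`); see
#'   [read_edge_list()].
#' @param gene_ids Gene universe of the output.
#' @return Tibble with columns `gene_id`, `network_weight` (0 for isolated
#'   genes).
#' @export
network_weight <- function(edges, gene_ids) {
  edges <- as_edge_list(edges)
  incident <- dplyr::bind_rows(
    tibble::tibble(gene_id = edges$gene_a, w = edges$weight),
    tibble::tibble(gene_id = edges$gene_b[edges$gene_b != edges$gene_a],
                   w = edges$weight[edges$gene_b != edges$gene_a])
  ) |>
    dplyr::summarise(network_weight = sum(.data$w), .by = "gene_id")
  tibble::tibble(gene_id = as.character(gene_ids)) |>
    dplyr::left_join(incident, by = "gene_id") |>
    dplyr::mutate(network_weight = dplyr::coalesce(.data$network_weight, 0))
}

#' High-level functional category vocabulary
#'
#' Molecular-function annotations are aggregated to coarse groups before use
#' as features, to blunt the effect of inaccurate fine-grained annotations:
#' five molecular roles (transcription factor, receptor, kinase, transporter,
#' enzyme), thirteen metabolic domains for genes classified in a metabolic
#' pathway database, plus `other_metabolism` (enzymes unclassified there) and
#' `macromolecule_metabolism` (enzymes absent from the pathway database,
#' predominantly macromolecule metabolism).
#'
#' @return Character vector of valid category labels.
#' @export
category_vocabulary <- function() {
  c("transcription_factor", "receptor", "kinase", "transporter", "enzyme",
    "carbohydrate_metabolism", "nucleotide_metabolism", "amino_acid_metabolism",
    "lipid_metabolism", "cofactor_metabolism", "secondary_metabolism",
    "energy_metabolism", "hormone_metabolism", "cell_wall_metabolism",
    "detoxification", "inorganic_nutrient_metabolism", "redox_metabolism",
    "polyamine_metabolism",
    "other_metabolism", "macromolecule_metabolism")
}

#' Read a gene-to-category map
#'
#' @param path TSV with columns `gene_id` and `labels` (comma-separated
#'   category labels; empty for unannotated genes).
#' @return Tibble with `gene_id` and list-column `labels`.
#' @export
read_category_map <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("gene_id", "labels") %in% names(df))) {
    stop("category map needs columns gene_id, labels")
  }
  df$labels[is.na(df$labels)] <- ""
  df$labels <- lapply(strsplit(df$labels, ",", fixed = TRUE), trimws)
  df$labels <- lapply(df$labels, function(l) l[nzchar(l)])
  tibble::as_tibble(df)
}

#' Binary functional-category features
#'
#' One `is_<label>` column per label in [category_vocabulary()], set to 1 iff
#' the gene carries that label in the category map.
#'
#' @param cmap Category map: tibble with `gene_id` and list-column `labels`
#'   (see [read_category_map()]).
#' @param gene_ids Gene universe of the output.
#' @param vocabulary Labels to emit columns for; defaults to the full
#'   vocabulary.
#' @return Feature-table tibble over `gene_ids`.
#' @export
go_category_features <- function(cmap, gene_ids,
                                 vocabulary = category_vocabulary()) {
  all_labels <- unique(unlist(cmap$labels))
  bad <- setdiff(all_labels, category_vocabulary())
  if (length(bad)) stop("unknown category label(s): ", paste(bad, collapse = ", "))
  out <- tibble::tibble(gene_id = as.character(gene_ids))
  idx <- match(out$gene_id, cmap$gene_id)
  for (lab in vocabulary) {
    has <- vapply(idx, function(i) {
      !is.na(i) && lab %in% cmap$labels[[i]]
    }, logical(1))
    out[[paste0("is_", lab)]] <- as.numeric(has)
  }
  out
}

#' Assemble a full feature table from partial tables
#'
#' Joins partial feature tables (polymorphism, network, category) and
#' passthrough columns (e.g. `paralog_copy_number`, `is_essential_gene` taken
#' from published predictions) into one table over a common gene universe.
#' Genes missing from a part are filled with `fill` (default 0), with a
#' message reporting how many cells were filled; this pipeline has
#' no principled imputation for these features, so absence is treated as zero
#' signal.
#'
#' @param ... Partial tables, each a data frame with `gene_id` plus feature
#'   columns. Duplicate feature columns across parts are an error.
#' @param gene_ids Gene universe; defaults to the union of all parts' ids.
#' @param schema Optional [feature_schema()] for final validation.
#' @param fill Value used for genes absent from a part.
#' @return A validated `qtg_feature_table`.
#' @export
assemble_feature_table <- function(..., gene_ids = NULL, schema = NULL, fill = 0) {
  parts <- list(...)
  if (!length(parts)) stop("no partial tables supplied")
  cols <- unlist(lapply(parts, function(p) setdiff(names(p), "gene_id")))
  dup <- unique(cols[duplicated(cols)])
  if (length(dup)) stop("conflicting duplicate column(s): ", paste(dup, collapse = ", "))
  if (is.null(gene_ids)) {
    gene_ids <- sort(unique(unlist(lapply(parts, function(p) p$gene_id))))
  }
  out <- tibble::tibble(gene_id = as.character(gene_ids))
  for (p in parts) {
    p <- tibble::as_tibble(p)
    p$gene_id <- as.character(p$gene_id)
    out <- dplyr::left_join(out, p, by = "gene_id")
  }
  n_filled <- sum(is.na(as.matrix(out[, -1, drop = FALSE])))
  if (n_filled > 0) {
    message("assemble_feature_table: filled ", n_filled,
            " missing cell(s) with ", fill)
    out <- dplyr::mutate(out, dplyr::across(-"gene_id",
                                            ~ dplyr::coalesce(.x, fill)))
  }
  as_feature_table(out, schema = schema)
}
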