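#' Read gene models from a GFF3 file
#'
#' Parses a GFF3 genome annotation and keeps one record per gene-type feature.
#' Coordinates follow the GFF3 convention: 1-based, inclusive. Strand is
#' carried through but ignored by every downstream computation.
#'
#' @param path Path to a GFF3 file.
#' @param feature_type GFF3 `type` values treated as genes (default `"gene"`).
#' @return A tibble of class `qtg_annotation` with columns `gene_id`,
#'   `chromosome`, `start`, `end`, `strand`, sorted by chromosome then start.
#'   The number of rows is the genome gene count.
#' @export
read_genome_annotation <- function(path, feature_type = "gene") {
  raw <- readLines(path, warn = FALSE)
  body <- which(!startsWith(raw, "#") & nzchar(trimws(raw)))
  if (!length(body)) {
    return(new_annotation(tibble::tibble(
      gene_id = character(), chromosome = character(),
      start = integer(), end = integer(), strand = character()
    )))
  }
  # validate coordinates up front so errors can cite the offending line
  for (i in body) {
    f <- strsplit(raw[i], "\t", fixed = TRUE)[[1]]
    if (length(f) >= 5) {
      s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
      if (!is.na(s) && !is.na(e) && s > e) {
        stop(sprintf("malformed coordinates (start %s > end %s) at line %d of %s",
                     f[4], f[5], i, path))
      }
    }
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_type]
  ids <- gr$ID
  if (is.null(ids)) ids <- gr$Name
  if (is.null(ids)) ids <- paste0("gene", seq_along(gr))
  ids <- sub("^gene:", "", as.character(ids))
  ann <- tibble::tibble(
    gene_id = ids,
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  ann$strand[ann$strand == "*"] <- "."
  new_annotation(ann)
}

new_annotation <- function(ann) {
  dup <- unique(ann$gene_id[duplicated(ann$gene_id)])
  if (length(dup)) stop("duplicate gene id(s) in annotation: ",
                        paste(dup, collapse = ", "))
  ann <- dplyr::arrange(ann, .data$chromosome, .data$start, .data$gene_id)
  structure(ann, class = c("qtg_annotation", class(tibble::as_tibble(ann))))
}

#' Build an annotation from a data frame of gene models
#'
#' Convenience constructor used by the fixture generator and by users whose
#' annotation is already tabular.
#'
#' @param df Data frame with columns `gene_id`, `chromosome`, `start`, `end`
#'   and optionally `strand`.
#' @return A `qtg_annotation` tibble (see [read_genome_annotation()]).
#' @export
as_genome_annotation <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("gene_id", "chromosome", "start", "end")
  if (!all(need %in% names(df))) {
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  }
  if (!"strand" %in% names(df)) df$strand <- "."
  if (any(df$start > df$end)) {
    bad <- which(df$start > df$end)[1]
    stop(sprintf("gene %s has start > end", df$gene_id[bad]))
  }
  df$gene_id <- as.character(df$gene_id)
  df$chromosome <- as.character(df$chromosome)
  new_annotation(df[, c("gene_id", "chromosome", "start", "end", "strand")])
}

#' @export
print.qtg_annotation <- function(x, ...) {
  cat("<qtg_annotation> ", nrow(x), " genes on ",
      length(unique(x$chromosome)), " chromosome(s)\n", sep = "")
  NextMethod()
}

#' Read QTL interval definitions
#'
#' QTL regions are marker-bounded chromosome intervals: each row gives the
#' positions of the left and right flanking markers used to declare the QTL in
#' the mapping study. Marker-name resolution is out of scope; positions are
#' supplied directly.
#'
#' @param path TSV with columns `qtl_id`, `chromosome`, `left_marker_pos`,
#'   `right_marker_pos` and optionally `trait_label`.
#' @return A tibble with those columns.
#' @export
read_qtl_regions <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("qtl_id", "chromosome", "left_marker_pos", "right_marker_pos")
  if (!all(need %in% names(df))) {
    stop("QTL table needs columns: ", paste(need, collapse = ", "))
  }
  if (!"trait_label" %in% names(df)) df$trait_label <- ""
  if (any(df$left_marker_pos > df$right_marker_pos)) {
    stop("QTL with left_marker_pos > right_marker_pos: ",
         paste(df$qtl_id[df$left_marker_pos > df$right_marker_pos], collapse = ", "))
  }
  df$qtl_id <- as.character(df$qtl_id)
  df$chromosome <- as.character(df$chromosome)
  tibble::as_tibble(df[, c(need, "trait_label")])
}

trait_categories <- c("development", "abiotic stress", "biotic stress", "other")

#' Read a curated causal-gene catalog
#'
#' The catalog lists genes with experimental evidence of being the causal gene
#' of a mapped QTL, each labelled with one of four coarse trait categories:
#' development, abiotic stress, biotic stress, other.
#'
#' @param path TSV with columns `gene_id`, `trait_category` and optionally
#'   `evidence_note`.
#' @return A tibble with columns `gene_id`, `trait_category`, `evidence_note`.
#' @export
read_causal_genes <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene_id", "trait_category") %in% names(df))) {
    stop("causal-gene table needs columns gene_id, trait_category")
  }
  if (!"evidence_note" %in% names(df)) df$evidence_note <- ""
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup)) stop("duplicate causal gene(s): ", paste(dup, collapse = ", "))
  bad <- setdiff(unique(df$trait_category), trait_categories)
  if (length(bad)) {
    stop("unknown trait categor(ies): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(trait_categories, collapse = ", "))
  }
  tibble::as_tibble(df[, c("gene_id", "trait_category", "evidence_note")])
}

#' Read a co-function network edge list
#'
#' Edges are undirected and weighted (AraNet/RiceNet style). Files may list an
#' edge in both orientations or split its weight over several records;
#' duplicate undirected pairs are summed, which makes downstream node weights
#' invariant to how the file was laid out.
#'
#' @param path TSV with columns `gene_a`, `gene_b`, `weight`.
#' @return A tibble with one row per undirected pair (gene_a < gene_b) and the
#'   summed weight.
#' @export
read_edge_list <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene_a", "gene_b", "weight") %in% names(df))) {
    stop("edge list needs columns gene_a, gene_b, weight")
  }
  as_edge_list(df)
}

#' @rdname read_edge_list
#' @param df Data frame of edges to normalise in place of a file.
#' @export
as_edge_list <- function(df) {
  df <- tibble::as_tibble(df)
  if (any(df$weight < 0)) stop("negative edge weight(s) not allowed")
  df |>
    dplyr::mutate(a = pmin(.data$gene_a, .data$gene_b),
                  b = pmax(.data$gene_a, .data$gene_b)) |>
    dplyr::summarise(weight = sum(.data$weight), .by = c("a", "b")) |>
    dplyr::rename(gene_a = "a", gene_b = "b")
}

#' Genes contained in a QTL interval
#'
#' Returns the genes whose body overlaps the marker interval on the region's
#' chromosome, using inclusive-overlap: any overlap between the gene body and
#' `[left_marker_pos, right_marker_pos]` counts, so a gene spanning a marker
#' position is included. Candidate gene lists for ranking are built this way —
#' every gene between the bounding markers is a candidate.
#'
#' @param annotation A `qtg_annotation`.
#' @param region One-row data frame (or list) with `chromosome`,
#'   `left_marker_pos`, `right_marker_pos`.
#' @return Character vector of gene ids ordered by start position.
#' @export
genes_in_qtl <- function(annotation, region) {
  chrom <- as.character(region$chromosome)
  if (!chrom %in% annotation$chromosome) {
    stop("chromosome '", chrom, "' not present in annotation")
  }
  g <- annotation[annotation$chromosome == chrom, ]
  hits <- IRanges::overlapsAny(
    IRanges::IRanges(g$start, g$end),
    IRanges::IRanges(as.integer(region$left_marker_pos),
                     as.integer(region$right_marker_pos))
  )
  g$gene_id[hits][order(g$start[hits])]
}

#' Neighbouring genes in gene order
#'
#' The `k` genes nearest to a query gene in gene order on the same chromosome:
#' `ceiling(k/2)` upstream and `floor(k/2)` downstream, borrowing from the
#' other side near chromosome ends so the total is `min(k, available)`. The
#' query gene itself is never returned. Used to assemble the query-plus-200-
#' neighbours testing sets of the trait-category rank analysis.
#'
#' @param annotation A `qtg_annotation`.
#' @param gene_id Query gene id.
#' @param k Number of neighbours requested (non-negative).
#' @return Character vector of at most `k` gene ids, in chromosome order.
#' @export
flanking_genes <- function(annotation, gene_id, k) {
  stopifnot(k >= 0)
  row <- which(annotation$gene_id == gene_id)
  if (!length(row)) stop("unknown gene id: ", gene_id)
  chrom <- annotation$chromosome[row]
  g <- annotation$gene_id[annotation$chromosome == chrom]
  i <- which(g == gene_id)
  n_up_want <- ceiling(k / 2)
  n_dn_want <- floor(k / 2)
  avail_up <- i - 1L
  avail_dn <- length(g) - i
  n_up <- min(n_up_want, avail_up)
  n_dn <- min(n_dn_want, avail_dn)
  # borrow whatever one side could not supply from the other
  n_dn <- min(n_dn + (n_up_want - n_up), avail_dn)
  n_up <- min(n_up + (n_dn_want - min(n_dn_want, avail_dn)), avail_up)
  idx <- c(seq_len(n_up) + (i - n_up - 1L), i + seq_len(n_dn))
  g[idx]
}
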