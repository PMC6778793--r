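effect_tag_vocabulary <- c(
  "nonsynonymous", "nonsynonymous_deleterious", "start_lost", "start_gained",
  "stop_gained", "stop_lost", "splice_site", "cis_element"
)

# SnpEff ANN effect terms -> canonical effect tags. Canonical names pass
# through unchanged so pre-digested inputs need no mapping.
snpeff_effect_map <- c(
  missense_variant = "nonsynonymous",
  stop_gained = "stop_gained",
  stop_lost = "stop_lost",
  start_lost = "start_lost",
  initiator_codon_variant = "start_lost",
  `5_prime_UTR_premature_start_codon_gain_variant` = "start_gained",
  splice_donor_variant = "splice_site",
  splice_acceptor_variant = "splice_site",
  splice_region_variant = "splice_site"
)

map_effect_terms <- function(terms) {
  out <- character(0)
  for (t in terms) {
    if (t %in% effect_tag_vocabulary) out <- c(out, t)
    else if (t %in% names(snpeff_effect_map)) out <- c(out, unname(snpeff_effect_map[t]))
  }
  unique(out)
}

validate_variants <- function(df) {
  stopifnot(all(c("chromosome", "position", "gene_id", "effect_tags") %in% names(df)))
  if (!is.list(df$effect_tags)) {
    df$effect_tags <- strsplit(as.character(df$effect_tags), ",", fixed = TRUE)
  }
  df$effect_tags <- lapply(df$effect_tags, function(tags) {
    tags <- trimws(tags)
    bad <- setdiff(tags, effect_tag_vocabulary)
    if (length(bad)) stop("unknown effect tag(s): ", paste(bad, collapse = ", "))
    if (!length(tags)) stop("variant with empty effect_tags")
    # a deleterious call is by definition a nonsynonymous site
    if ("nonsynonymous_deleterious" %in% tags) tags <- union(tags, "nonsynonymous")
    unique(tags)
  })
  tibble::as_tibble(df[, c("chromosome", "position", "gene_id", "effect_tags")])
}

#' Read effect-annotated variant records
#'
#' Variants enter the pipeline already annotated for functional effect (the
#' output convention of SnpEff/SIFT-style annotators; the annotators
#' themselves are not run here). Two layouts are accepted:
#'
#' * `format = "tsv"`: pre-digested table with columns `chromosome`,
#'   `position`, `gene_id`, `effect_tags` (comma-separated canonical tags).
#' * `format = "vcf"`: a VCF whose INFO field carries a SnpEff-style `ANN`
#'   entry (`allele|effect|impact|gene_name|gene_id|...`, multiple entries
#'   comma-separated) and, optionally, a `SIFT` entry; a SIFT value containing
#'   `DELETERIOUS` marks the site's nonsynonymous change as deleterious.
#'
#' Canonical tags: `r paste(effect_tag_vocabulary, collapse = ", ")`. The
#' `cis_element` channel (motif-disrupting SNPs upstream of a gene) is consumed
#' as a precomputed tag.
#'
#' @param path Input file.
#' @param format `"tsv"` or `"vcf"` (default guessed from the extension).
#' @return A tibble with columns `chromosome`, `position`, `gene_id` and a
#'   list-column `effect_tags`; one row per (variant, affected gene).
#' @export
read_annotated_variants <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  format <- match.arg(format, c("tsv", "vcf"))
  if (format == "tsv") {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    return(validate_variants(df))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  ann <- vcfR::extract.info(vcf, element = "ANN")
  sift <- vcfR::extract.info(vcf, element = "SIFT")
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    if (is.na(ann[i])) next
    deleterious <- !is.na(sift[i]) && grepl("DELETERIOUS", sift[i], fixed = TRUE)
    for (entry in strsplit(ann[i], ",", fixed = TRUE)[[1]]) {
      f <- strsplit(entry, "|", fixed = TRUE)[[1]]
      if (length(f) < 5) next
      effects <- strsplit(f[2], "&", fixed = TRUE)[[1]]
      tags <- map_effect_terms(effects)
      if (deleterious && "nonsynonymous" %in% tags) {
        tags <- union(tags, "nonsynonymous_deleterious")
      }
      if (!length(tags)) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chromosome = fix$CHROM[i],
        position = as.integer(fix$POS[i]),
        gene_id = f[5],
        effect_tags = list(tags)
      )
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(chromosome = character(), position = integer(),
                          gene_id = character(), effect_tags = list()))
  }
  validate_variants(dplyr::bind_rows(rows))
}

#' Write annotated variants to the pre-digested TSV layout
#'
#' @param variants Tibble as returned by [read_annotated_variants()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotated_variants <- function(variants, path) {
  out <- variants
  out$effect_tags <- vapply(out$effect_tags, paste, character(1), collapse = ",")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
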