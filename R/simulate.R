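#' Default planted-effect specification for synthetic fixtures
#'
#' One row per feature of the synthetic schema, declaring how the feature is
#' generated and how much it differs between causal and background genes:
#'
#' * `bernoulli` — binary flag with background frequency `background`; causal
#'   genes use `background * effect` (an enrichment/depletion ratio).
#' * `poisson` — count with background mean `background`; causal mean is
#'   `background * effect`.
#' * `poisson_rate` — per-amino-acid rate: a count is drawn with mean
#'   `background * protein_length`, and the feature is count/length; causal
#'   genes use rate `background * effect`.
#' * `bernoulli_given_nonsyn` — flag drawn only for genes with at least one
#'   nonsynonymous variant (a deleterious call presupposes one).
#' * `derived` — computed from generated raw artifacts (network weight from
#'   edges); no planted signal.
#'
#' The default plants signal on the features reported as most informative for
#' real causal genes — paralog copy number, transporter, transcription factor,
#' receptor, premature stop codons and nonsynonymous SNP load — with
#' enrichment ratios in the 2-4x range typical of causal-vs-background
#' contrasts, a mild depletion of essential genes, and everything else pure
#' noise.
#'
#' @return Tibble with columns `feature`, `family`, `background`, `effect`.
#' @export
default_effect_spec <- function() {
  tibble::tribble(
    ~feature,                     ~family,                  ~background, ~effect,
    "normalized_nonsyn_SNP",      "poisson_rate",           0.02,        2.0,
    "is_nonsyn_deleterious",      "bernoulli_given_nonsyn", 0.30,        1.0,
    "is_start_lost",              "bernoulli",              0.02,        1.0,
    "is_start_gained",            "bernoulli",              0.03,        1.0,
    "is_stop_gained",             "bernoulli",              0.10,        3.0,
    "is_stop_lost",               "bernoulli",              0.02,        1.0,
    "is_splice_site",             "bernoulli",              0.05,        1.0,
    "is_SNP_cis",                 "bernoulli",              0.15,        1.0,
    "is_transcription_factor",    "bernoulli",              0.06,        3.0,
    "is_receptor",                "bernoulli",              0.05,        2.0,
    "is_kinase",                  "bernoulli",              0.05,        1.0,
    "is_transporter",             "bernoulli",              0.05,        4.0,
    "is_macromolecule_metabolism","bernoulli",              0.15,        1.0,
    "is_other_metabolism",        "bernoulli",              0.08,        1.0,
    "network_weight",             "derived",                NA,          1.0,
    "paralog_copy_number",        "poisson",                1.5,         2.5,
    "is_essential_gene",          "bernoulli",              0.10,        0.5
  )
}

#' Null effect specification (no planted signal)
#'
#' All enrichment ratios 1: causal genes are statistically indistinguishable
#' from background, so any downstream classifier should score at chance
#' (AUC-ROC 0.5).
#'
#' @return Effect-spec tibble as in [default_effect_spec()].
#' @export
null_effect_spec <- function() {
  dplyr::mutate(default_effect_spec(), effect = 1.0)
}

#' Declare a synthetic fixture
#'
#' Parameters of a fully synthetic test genome: gene models on several
#' chromosomes, a feature table with planted causal-gene enrichments, the raw
#' artifacts the features derive from (effect-annotated variants, co-function
#' edges, category map, passthrough columns), a causal-gene catalog with trait
#' categories, and marker-bounded QTL intervals each containing exactly one
#' causal gene.
#'
#' @param n_genes Total genes (default 2,000 — minutes-scale for CI).
#' @param n_chromosomes Chromosome count.
#' @param n_causal Number of planted causal genes.
#' @param qtl_width Genes per QTL interval (the causal gene plus
#'   `qtl_width - 1` background genes).
#' @param effects Effect-spec tibble ([default_effect_spec()] or
#'   [null_effect_spec()]).
#' @param trait_props Named proportions over the four trait categories.
#' @param category_effects Optional named multipliers applied to the planted
#'   effect of causal genes of a given trait category (e.g.
#'   `c("abiotic stress" = 1.5)` makes abiotic-stress causal genes easier to
#'   rank); categories absent from the vector use 1.
#' @param mean_gene_length,mean_gap Mean gene body length and intergenic gap
#'   (bp).
#' @param mean_degree Mean co-function edges per gene.
#' @param cap_binary Acknowledge capping of causal binary frequencies at 1;
#'   without it, a requested `background * effect > 1` is an error.
#' @param seed Integer seed; the whole bundle is a pure function of the spec.
#' @return A `qtg_fixture_spec` list.
#' @export
fixture_spec <- function(n_genes = 2000, n_chromosomes = 5, n_causal = 40,
                         qtl_width = 40, effects = default_effect_spec(),
                         trait_props = c("development" = 0.40,
                                         "abiotic stress" = 0.25,
                                         "biotic stress" = 0.20,
                                         "other" = 0.15),
                         category_effects = NULL,
                         mean_gene_length = 3000, mean_gap = 2000,
                         mean_degree = 4, cap_binary = FALSE, seed = 1) {
  stopifnot(n_causal > 0, n_causal < n_genes, qtl_width >= 1,
            n_genes >= n_causal * qtl_width)
  stopifnot(setequal(names(trait_props), trait_categories))
  bern <- effects$family %in% c("bernoulli", "bernoulli_given_nonsyn")
  if (any(effects$background[bern] <= 0 | effects$background[bern] >= 1)) {
    stop("binary background frequencies must lie in (0, 1)")
  }
  if (any(effects$effect < 0, na.rm = TRUE)) stop("effects must be >= 0")
  over <- bern & effects$background * effects$effect > 1
  if (any(over) && !cap_binary) {
    stop("requested causal frequency > 1 for: ",
         paste(effects$feature[over], collapse = ", "),
         " (set cap_binary = TRUE to cap at 1)")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_chromosomes = as.integer(n_chromosomes),
                 n_causal = as.integer(n_causal),
                 qtl_width = as.integer(qtl_width),
                 effects = effects, trait_props = trait_props,
                 category_effects = category_effects,
                 mean_gene_length = mean_gene_length, mean_gap = mean_gap,
                 mean_degree = mean_degree, cap_binary = cap_binary,
                 seed = as.integer(seed)),
            class = "qtg_fixture_spec")
}

causal_param <- function(family, background, effect, mult = 1) {
  if (family %in% c("bernoulli", "bernoulli_given_nonsyn")) {
    pmin(background * effect * mult, 1)
  } else {
    background * effect * mult
  }
}

#' Generate a synthetic fixture bundle
#'
#' Deterministically generates, from the spec's seed, every input the pipeline
#' consumes: a genome annotation, annotated variants, co-function edges, a
#' functional category map, passthrough columns, the assembled feature table
#' (recomputed from those raw artifacts through the feature-extraction
#' functions, so extraction and generation agree exactly), a causal-gene
#' catalog, QTL intervals each containing exactly one causal gene, and a truth
#' record with everything an oracle needs.
#'
#' @param spec A [fixture_spec()].
#' @return A `qtg_fixture` list: `annotation`, `feature_table`, `catalog`,
#'   `qtl`, `edges`, `variants`, `category_map`, `protein_lengths`,
#'   `passthrough`, `truth`, `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "qtg_fixture_spec"))
  withr::with_seed(spec$seed, generate_fixture_impl(spec))
}

generate_fixture_impl <- function(spec) {
  n <- spec$n_genes
  ids <- sprintf("g%05d", seq_len(n))
  chrom <- sort(rep_len(sprintf("chr%d", seq_len(spec$n_chromosomes)), n))

  glen <- pmax(200L, as.integer(round(stats::rlnorm(n, log(spec$mean_gene_length), 0.3))))
  gap <- pmax(50L, as.integer(round(stats::rexp(n, 1 / spec$mean_gap))))
  ann <- tibble::tibble(gene_id = ids, chromosome = chrom) |>
    dplyr::mutate(.by = "chromosome",
                  start = cumsum(dplyr::lag(glen[match(.data$gene_id, ids)], default = 0L) +
                                   gap[match(.data$gene_id, ids)]),
                  end = .data$start + glen[match(.data$gene_id, ids)] - 1L,
                  strand = rep_len(c("+", "-"), dplyr::n()))
  annotation <- as_genome_annotation(ann)
  # annotation is sorted (chrom, start); ids were assigned in that order
  stopifnot(identical(annotation$gene_id, ids))

  prot_len <- pmax(50L, as.integer(round(stats::rlnorm(n, log(400), 0.4))))
  names(prot_len) <- ids

  # causal genes spaced >= qtl_width apart in gene order so each QTL window
  # of qtl_width consecutive genes holds exactly one causal gene
  # causal genes spaced >= qtl_width apart in gene order, so a qtl_width
  # window containing one causal gene can never contain a second
  per_chr <- split(seq_len(n), chrom)
  w <- spec$qtl_width
  causal_idx <- integer(0)
  quota <- spec$n_causal
  for (k in seq_along(per_chr)) {
    idx <- per_chr[[k]]
    cap <- floor(length(idx) / w)
    take <- if (k == length(per_chr)) quota else
      min(quota, round(spec$n_causal * length(idx) / n), cap)
    take <- min(take, cap)
    if (take > 0) {
      y <- sort(sample.int(length(idx) - (take - 1L) * (w - 1L), take))
      pos <- y + (seq_len(take) - 1L) * (w - 1L)
      causal_idx <- c(causal_idx, idx[pos])
      quota <- quota - take
    }
  }
  if (quota > 0) stop("could not place all causal genes; increase n_genes or reduce qtl_width")
  causal_idx <- sort(causal_idx)
  causal <- as.integer(seq_len(n) %in% causal_idx)

  cats <- sample(trait_categories, spec$n_causal, replace = TRUE,
                 prob = spec$trait_props[trait_categories])
  catalog <- tibble::tibble(gene_id = ids[causal_idx], trait_category = cats,
                            evidence_note = "synthetic planted causal gene")

  mult <- rep(1, n)
  if (!is.null(spec$category_effects)) {
    mm <- spec$category_effects[cats]
    mm[is.na(mm)] <- 1
    mult[causal_idx] <- mm
  }

  eff <- spec$effects
  draw <- list()
  nonsyn_counts <- integer(n)
  for (j in seq_len(nrow(eff))) {
    f <- eff$feature[j]; fam <- eff$family[j]
    bg <- eff$background[j]; e <- eff$effect[j]
    par_c <- causal_param(fam, bg, e, mult)
    par <- ifelse(causal == 1, par_c, bg)
    if (fam == "bernoulli") {
      draw[[f]] <- stats::rbinom(n, 1, par)
    } else if (fam == "poisson") {
      draw[[f]] <- stats::rpois(n, par)
    } else if (fam == "poisson_rate") {
      k <- stats::rpois(n, par * prot_len)
      if (f == "normalized_nonsyn_SNP") nonsyn_counts <- k
      draw[[f]] <- k / prot_len
    } else if (fam == "bernoulli_given_nonsyn") {
      draw[[f]] <- ifelse(nonsyn_counts >= 1, stats::rbinom(n, 1, par), 0L)
    } else if (fam == "derived") {
      draw[[f]] <- NULL
    } else stop("unknown effect family: ", fam)
  }

  variants <- build_variants(ids, annotation, draw, nonsyn_counts)
  edges <- build_edges(ids, spec$mean_degree)
  cmap <- build_category_map(ids, draw)

  passthrough <- tibble::tibble(
    gene_id = ids,
    paralog_copy_number = draw$paralog_copy_number,
    is_essential_gene = draw$is_essential_gene
  )

  go_vocab <- c("transcription_factor", "receptor", "kinase", "transporter",
                "macromolecule_metabolism", "other_metabolism")
  feature_table <- assemble_feature_table(
    polymorphism_features(variants, prot_len, ids),
    network_weight(edges, ids),
    go_category_features(cmap, ids, vocabulary = go_vocab),
    passthrough,
    gene_ids = ids
  )

  qtl <- build_qtl(annotation, ids, causal_idx, cats, spec$qtl_width)

  truth <- tibble::tibble(gene_id = ids, causal = causal,
                          protein_length = unname(prot_len),
                          category_multiplier = mult)
  structure(list(annotation = annotation, feature_table = feature_table,
                 catalog = catalog, qtl = qtl, edges = edges,
                 variants = variants, category_map = cmap,
                 protein_lengths = tibble::tibble(gene_id = ids,
                                                  protein_length = unname(prot_len)),
                 passthrough = passthrough, truth = truth, spec = spec),
            class = "qtg_fixture")
}

build_variants <- function(ids, annotation, draw, nonsyn_counts) {
  flag_tag <- c(is_nonsyn_deleterious = "nonsynonymous_deleterious",
                is_start_lost = "start_lost", is_start_gained = "start_gained",
                is_stop_gained = "stop_gained", is_stop_lost = "stop_lost",
                is_splice_site = "splice_site", is_SNP_cis = "cis_element")
  n <- length(ids)
  # one flat (gene index, tag) record per variant, vectorised
  gene_of <- integer(0)
  tags <- list()
  if (any(nonsyn_counts > 0)) {
    g <- rep(seq_len(n), nonsyn_counts)
    tg <- rep(list("nonsynonymous"), length(g))
    # the first nonsyn variant of a flagged gene carries the deleterious call
    first <- match(which(draw$is_nonsyn_deleterious == 1 & nonsyn_counts > 0), g)
    for (i in first) tg[[i]] <- c("nonsynonymous", "nonsynonymous_deleterious")
    gene_of <- c(gene_of, g); tags <- c(tags, tg)
  }
  for (fl in setdiff(names(flag_tag), "is_nonsyn_deleterious")) {
    g <- which(draw[[fl]] == 1)
    gene_of <- c(gene_of, g)
    tags <- c(tags, rep(list(flag_tag[[fl]]), length(g)))
  }
  if (!length(gene_of)) {
    return(validate_variants(tibble::tibble(
      chromosome = character(), position = integer(),
      gene_id = character(), effect_tags = list()
    )))
  }
  width <- annotation$end[gene_of] - annotation$start[gene_of]
  pos <- annotation$start[gene_of] +
    as.integer(floor(stats::runif(length(gene_of)) * (width + 1)))
  out <- tibble::tibble(chromosome = annotation$chromosome[gene_of],
                        position = pos, gene_id = ids[gene_of],
                        effect_tags = tags)
  out <- out[order(out$gene_id, out$position), ]
  validate_variants(out)
}

build_edges <- function(ids, mean_degree) {
  n <- length(ids)
  deg <- stats::rpois(n, mean_degree / 2)
  from <- rep(seq_len(n), deg)
  to <- sample.int(n, length(from), replace = TRUE)
  keep <- from != to
  tibble::tibble(gene_a = ids[from[keep]], gene_b = ids[to[keep]],
                 weight = round(stats::rexp(sum(keep), 1), 4)) |>
    as_edge_list()
}

build_category_map <- function(ids, draw) {
  labs <- c(is_transcription_factor = "transcription_factor",
            is_receptor = "receptor", is_kinase = "kinase",
            is_transporter = "transporter",
            is_macromolecule_metabolism = "macromolecule_metabolism",
            is_other_metabolism = "other_metabolism")
  labels <- lapply(seq_along(ids), function(i) {
    unname(labs[vapply(names(labs), function(fl) draw[[fl]][i] == 1, logical(1))])
  })
  tibble::tibble(gene_id = ids, labels = labels)
}

build_qtl <- function(annotation, ids, causal_idx, cats, width) {
  per_chr_idx <- split(seq_along(ids), annotation$chromosome)
  purrr::map_dfr(seq_along(causal_idx), function(q) {
    i <- causal_idx[q]
    chr <- annotation$chromosome[i]
    idx <- per_chr_idx[[chr]]
    pos_in_chr <- match(i, idx)
    lo_min <- max(1L, pos_in_chr - width + 1L)
    lo_max <- min(pos_in_chr, length(idx) - width + 1L)
    lo <- if (lo_max > lo_min) sample(lo_min:lo_max, 1) else lo_min
    window <- idx[lo:(lo + width - 1L)]
    tibble::tibble(qtl_id = sprintf("QTL%03d", q),
                   chromosome = chr,
                   left_marker_pos = annotation$start[window[1]],
                   right_marker_pos = annotation$end[window[length(window)]],
                   trait_label = cats[q],
                   causal_gene = ids[i])
  })
}

#' Bayes-optimal score of a fixture gene
#'
#' The exact log-likelihood ratio of causal vs background for each gene's
#' realised features under the fixture's generative model (independent
#' features given the label). By the Neyman-Pearson lemma, ranking by this
#' score is the best any classifier can do on the fixture, so it calibrates
#' what AUC a trained model can be expected to reach. Derived features
#' (network weight) and per-category effect multipliers contribute nothing /
#' are evaluated at the base effect.
#'
#' @param bundle A `qtg_fixture` from [generate_fixture()].
#' @param gene_ids Genes to score (default: all).
#' @return Tibble `gene_id`, `llr` (0 everywhere for a null spec).
#' @export
bayes_optimal_score <- function(bundle, gene_ids = NULL) {
  stopifnot(inherits(bundle, "qtg_fixture"))
  gene_ids <- gene_ids %||% bundle$truth$gene_id
  unknown <- setdiff(gene_ids, bundle$truth$gene_id)
  if (length(unknown)) stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  tab <- bundle$feature_table
  row <- match(gene_ids, tab$gene_id)
  L <- bundle$truth$protein_length[match(gene_ids, bundle$truth$gene_id)]
  eff <- bundle$spec$effects
  llr <- numeric(length(gene_ids))
  for (j in seq_len(nrow(eff))) {
    f <- eff$feature[j]; fam <- eff$family[j]
    bg <- eff$background[j]; e <- eff$effect[j]
    if (fam == "derived" || e == 1) next
    x <- tab[[f]][row]
    if (fam == "bernoulli" || fam == "bernoulli_given_nonsyn") {
      p1 <- min(bg * e, 1); p0 <- bg
      term <- x * log(p1 / p0) + (1 - x) * log((1 - p1) / (1 - p0))
      if (fam == "bernoulli_given_nonsyn") {
        k <- tab$normalized_nonsyn_SNP[row] * L
        term[round(k) < 1] <- 0
      }
      llr <- llr + term
    } else if (fam == "poisson") {
      l1 <- bg * e; l0 <- bg
      llr <- llr + x * log(l1 / l0) - (l1 - l0)
    } else if (fam == "poisson_rate") {
      k <- round(x * L)
      l1 <- bg * e * L; l0 <- bg * L
      llr <- llr + k * log(l1 / l0) - (l1 - l0)
    }
  }
  tibble::tibble(gene_id = gene_ids, llr = llr)
}

#' Write a fixture bundle to standard-format files
#'
#' Emits everything as the plain-text formats the readers consume: `genes.gff3`
#' (annotation), `features.tsv`, `causal_genes.tsv`, `qtl.tsv`, `edges.tsv`,
#' `variants.tsv` and `variants.vcf` (SnpEff-style ANN/SIFT INFO fields),
#' `category_map.tsv`, `protein_lengths.tsv`, `passthrough.tsv`, `truth.tsv`.
#' Output is byte-identical across runs with the same spec.
#'
#' @param bundle A `qtg_fixture`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_gff3(bundle$annotation, p("genes.gff3"))
  write_feature_table(bundle$feature_table, p("features.tsv"))
  readr::write_tsv(bundle$catalog, p("causal_genes.tsv"), progress = FALSE)
  readr::write_tsv(bundle$qtl, p("qtl.tsv"), progress = FALSE)
  readr::write_tsv(bundle$edges, p("edges.tsv"), progress = FALSE)
  write_annotated_variants(bundle$variants, p("variants.tsv"))
  write_variants_vcf(bundle$variants, p("variants.vcf"))
  cm <- bundle$category_map
  cm$labels <- vapply(cm$labels, paste, character(1), collapse = ",")
  readr::write_tsv(cm, p("category_map.tsv"), progress = FALSE)
  readr::write_tsv(bundle$protein_lengths, p("protein_lengths.tsv"), progress = FALSE)
  readr::write_tsv(bundle$passthrough, p("passthrough.tsv"), progress = FALSE)
  readr::write_tsv(bundle$truth, p("truth.tsv"), progress = FALSE)
  invisible(dir)
}

write_gff3 <- function(annotation, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tqtgrank\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     annotation$chromosome, annotation$start, annotation$end,
                     annotation$strand, annotation$gene_id))
  writeLines(lines, path)
  invisible(path)
}

# Minimal VCF 4.2 with SnpEff-style ANN entries and a SIFT INFO key; the
# canonical-tag -> SnpEff-term mapping inverts the reader's.
write_variants_vcf <- function(variants, path) {
  tag_term <- c(nonsynonymous = "missense_variant", stop_gained = "stop_gained",
                stop_lost = "stop_lost", start_lost = "start_lost",
                start_gained = "5_prime_UTR_premature_start_codon_gain_variant",
                splice_site = "splice_region_variant", cis_element = "cis_element")
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations: 'Allele|Annotation|Annotation_Impact|Gene_Name|Gene_ID'\">",
    "##INFO=<ID=SIFT,Number=1,Type=String,Description=\"SIFT prediction\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- vapply(seq_len(nrow(variants)), function(i) {
    tags <- variants$effect_tags[[i]]
    terms <- unname(tag_term[setdiff(tags, "nonsynonymous_deleterious")])
    ann <- sprintf("ANN=T|%s|MODERATE|%s|%s", paste(terms, collapse = "&"),
                   variants$gene_id[i], variants$gene_id[i])
    info <- if ("nonsynonymous_deleterious" %in% tags) {
      paste0(ann, ";SIFT=DELETERIOUS")
    } else ann
    sprintf("%s\t%d\t.\tA\tT\t.\tPASS\t%s", variants$chromosome[i],
            variants$position[i], info)
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
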