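#' Configure the prediction ensemble
#'
#' The production ranking path trains many classifiers, each on *all* known
#' causal genes plus a fresh random draw of negatives from the rest of the
#' genome, and ranks candidate genes by how often the ensemble votes them
#' "causal". 5,000 resampled models make it overwhelmingly likely that every
#' gene in a genome-scale negative pool is drawn into training at least once;
#' a few hundred models are adequate for small fixtures and testing.
#'
#' @param n_models Number of resampled models (default 5,000; use ~200 as a
#'   fast mode on small data).
#' @param train_neg_ratio Training negatives per positive (species profile:
#'   20 Arabidopsis-like, 5 rice-like).
#' @param classifier A [classifier_spec()].
#' @param decision_threshold Probability cutoff for a model's "causal" vote.
#' @param master_seed Integer seed; model `m` uses a seed derived from
#'   `(master_seed, m)`, so frequencies are identical however the models are
#'   batched.
#' @return A `qtg_ensemble_config` list.
#' @export
ensemble_config <- function(n_models = 5000, train_neg_ratio = 20,
                            classifier = classifier_spec(),
                            decision_threshold = 0.5, master_seed = 1) {
  stopifnot(n_models >= 1, train_neg_ratio >= 1,
            decision_threshold > 0, decision_threshold < 1)
  structure(list(n_models = as.integer(n_models),
                 train_neg_ratio = train_neg_ratio,
                 classifier = classifier,
                 decision_threshold = decision_threshold,
                 master_seed = as.integer(master_seed)),
            class = "qtg_ensemble_config")
}

#' Train a negative-resampling ensemble
#'
#' Fits `n_models` classifiers; every model is trained on all positives plus
#' `length(positives) * train_neg_ratio` negatives drawn uniformly without
#' replacement from the genome minus the positives (minus `exclude`).
#'
#' @param table Feature table covering the genome.
#' @param positives Known causal gene ids used as the positive class of every
#'   model.
#' @param config An [ensemble_config()].
#' @param exclude Gene ids barred from the negative pool — e.g. the known
#'   causal gene of a QTL about to be scored, so a gene under validation never
#'   leaks into training as a negative.
#' @return A `qtg_ensemble` (opaque list of fitted models plus bookkeeping).
#' @export
train_ensemble <- function(table, positives, config = ensemble_config(),
                           exclude = NULL) {
  positives <- as.character(positives)
  if (!length(positives)) stop("no positives to train on")
  stopifnot(all(positives %in% table$gene_id))
  m <- feature_matrix(table)
  pool <- setdiff(table$gene_id, union(positives, exclude))
  n_neg <- round(length(positives) * config$train_neg_ratio)
  if (length(pool) < n_neg) {
    stop(sprintf("insufficient negative pool: need %d, have %d", n_neg, length(pool)))
  }
  xpos <- m[positives, , drop = FALSE]
  models <- vector("list", config$n_models)
  for (i in seq_len(config$n_models)) {
    negs <- withr::with_seed(derive_seed(config$master_seed, i, 0L, 4L),
                             sample(pool, n_neg))
    x <- rbind(xpos, m[negs, , drop = FALSE])
    y <- rep(c(1L, 0L), c(length(positives), n_neg))
    models[[i]] <- fit_classifier(config$classifier, x, y,
                                  derive_seed(config$master_seed, i, 0L, 5L))
  }
  structure(list(models = models, config = config,
                 positives = positives, features = colnames(m)),
            class = "qtg_ensemble")
}

#' @export
print.qtg_ensemble <- function(x, ...) {
  cat("<qtg_ensemble>", length(x$models), "models,",
      length(x$positives), "positives,",
      "neg ratio", x$config$train_neg_ratio, "\n")
  invisible(x)
}

#' Ensemble prediction frequency per gene
#'
#' The fraction of ensemble models whose predicted causal probability reaches
#' the decision threshold — the ranking score. Scoring many genes in one call
#' amortises per-model prediction overhead; when several QTL are ranked
#' against the same ensemble, compute frequencies for the union of their genes
#' once and pass them to [rank_qtl_genes()].
#'
#' @param ensemble A trained [train_ensemble()] object.
#' @param table Feature table containing the genes.
#' @param gene_ids Genes to score.
#' @return Named numeric vector of frequencies in \[0, 1\].
#' @export
prediction_frequency <- function(ensemble, table, gene_ids) {
  gene_ids <- as.character(gene_ids)
  stopifnot(all(gene_ids %in% table$gene_id))
  m <- feature_matrix(table)[gene_ids, , drop = FALSE]
  votes <- vapply(ensemble$models, function(mod) {
    as.numeric(predict_prob(mod, m) >= ensemble$config$decision_threshold)
  }, numeric(length(gene_ids)))
  if (length(gene_ids) == 1) votes <- matrix(votes, nrow = 1)
  stats::setNames(rowMeans(votes), gene_ids)
}

#' Rank the genes of a QTL by ensemble prediction frequency
#'
#' Each gene's score is the fraction of ensemble models that vote it "causal".
#' Genes are sorted by descending frequency (ties broken by gene id for
#' determinism); `rank_percentile` is the percentage of QTL genes with
#' strictly higher frequency, so the top gene has percentile 0 and tied genes
#' share a percentile. Because QTL sizes vary widely, percentiles — not raw
#' ranks — are the comparable quantity across QTL. Genes absent from the
#' feature table are kept, flagged, and ranked last with frequency 0 rather
#' than silently dropped.
#'
#' @param ensemble A trained [train_ensemble()] object.
#' @param table Feature table (same schema as training).
#' @param qtl_gene_ids Genes inside the QTL interval (see [genes_in_qtl()]).
#' @param frequencies Optional named vector of precomputed
#'   [prediction_frequency()] values covering the QTL genes, to amortise
#'   scoring across several QTL.
#' @return A `qtg_ranking` tibble: `gene_id`, `prediction_frequency`, `rank`,
#'   `rank_percentile`, `missing_features`.
#' @export
rank_qtl_genes <- function(ensemble, table, qtl_gene_ids, frequencies = NULL) {
  qtl_gene_ids <- as.character(qtl_gene_ids)
  if (!length(qtl_gene_ids)) stop("empty QTL gene list")
  known <- intersect(qtl_gene_ids, table$gene_id)
  absent <- setdiff(qtl_gene_ids, table$gene_id)
  if (length(absent)) {
    warning("gene(s) missing from feature table, ranked last with frequency 0: ",
            paste(absent, collapse = ", "))
  }
  if (is.null(frequencies)) {
    frequencies <- if (length(known)) prediction_frequency(ensemble, table, known)
  } else if (!all(known %in% names(frequencies))) {
    stop("precomputed frequencies missing gene(s): ",
         paste(setdiff(known, names(frequencies)), collapse = ", "))
  }
  freq <- c(
    stats::setNames(as.numeric(frequencies[known]), known),
    stats::setNames(rep(0, length(absent)), absent)
  )
  out <- tibble::tibble(
    gene_id = names(freq),
    prediction_frequency = unname(freq),
    missing_features = names(freq) %in% absent
  ) |>
    dplyr::arrange(dplyr::desc(.data$prediction_frequency), .data$gene_id) |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      rank_percentile = 100 *
        vapply(.data$prediction_frequency,
               function(f) sum(freq > f), numeric(1)) / dplyr::n(),
      .after = "prediction_frequency"
    )
  class(out) <- c("qtg_ranking", class(out))
  out
}

#' Fraction of causal genes recalled at a rank-percentile cutoff
#'
#' Given one validation ranking per known causal gene, the recall at a cutoff
#' is the fraction of causal genes whose rank percentile is strictly below it
#' (top `cutoff_percent`% of their QTL).
#'
#' @param validation Data frame with one row per causal gene and a
#'   `rank_percentile` column, or a bare numeric vector of percentiles.
#' @param cutoff_percent Cutoff in (0, 100].
#' @return Recall fraction in \[0, 1\].
#' @export
recall_at_cutoff <- function(validation, cutoff_percent) {
  stopifnot(cutoff_percent > 0, cutoff_percent <= 100)
  pct <- if (is.data.frame(validation)) validation$rank_percentile else validation
  if (!length(pct)) stop("empty validation set")
  mean(pct < cutoff_percent)
}

#' Probability of recalling at least K causal genes across N QTL
#'
#' A mapping study usually yields several QTL. If each QTL's top-ranked subset
#' recalls its causal gene independently with probability `p` (the single-QTL
#' recall at the chosen percentile cutoff), the number recovered across `N`
#' QTL is binomial, and the chance of recovering at least `K` is
#' `sum over x = K..N of choose(N, x) p^x (1-p)^(N-x)`.
#'
#' @param p Per-QTL recall probability at the cutoff.
#' @param N Number of QTL.
#' @param K Minimum number of causal genes recovered (0 <= K <= N; K = 0
#'   trivially gives 1).
#' @return Probability in \[0, 1\].
#' @export
#' @examples
#' multi_qtl_recall_probability(7 / 11, N = 5, K = 1)
multi_qtl_recall_probability <- function(p, N, K) {
  stopifnot(p >= 0, p <= 1, N >= 1)
  if (K > N) stop("K must not exceed N")
  if (K < 0) stop("K must be non-negative")
  if (K == 0) return(1)
  x <- K:N
  sum(choose(N, x) * p^x * (1 - p)^(N - x))
}

#' Leave-one-out rank test by trait category
#'
#' How well does the ranking work for different kinds of traits? Each curated
#' causal gene is tested exactly once: it is removed from the training
#' catalog, an ensemble is trained on the remaining causal genes (with the
#' held-out gene barred from the negative pool), and the held-out gene is
#' ranked among itself plus its `flank` nearest genes in gene order. Rank
#' percentiles are then aggregated by trait category.
#'
#' @param table Feature table over the genome.
#' @param catalog Causal-gene catalog (columns `gene_id`, `trait_category`).
#' @param annotation A `qtg_annotation` containing every catalog gene.
#' @param config An [ensemble_config()]; a few hundred models suffice here.
#' @param flank Number of neighbouring genes in the testing set (default 200).
#' @return A `qtg_trait_report`: `per_gene` tibble (gene, category, rank,
#'   percentile) and `by_category` summary tibble.
#' @export
trait_category_rank_test <- function(table, catalog, annotation,
                                     config = ensemble_config(), flank = 200) {
  if (nrow(catalog) < 2) stop("need at least 2 catalog genes (leave-one-out must retain a positive)")
  absent <- setdiff(catalog$gene_id, annotation$gene_id)
  if (length(absent)) stop("catalog gene(s) absent from annotation: ",
                           paste(absent, collapse = ", "))
  stopifnot(all(catalog$gene_id %in% table$gene_id))

  per_gene <- purrr::map_dfr(seq_len(nrow(catalog)), function(i) {
    g <- catalog$gene_id[i]
    train_pos <- setdiff(catalog$gene_id, g)
    ens <- train_ensemble(table, train_pos, config, exclude = g)
    test_set <- union(g, flanking_genes(annotation, g, flank))
    ranking <- rank_qtl_genes(ens, table, test_set)
    row <- ranking[ranking$gene_id == g, ]
    tibble::tibble(gene_id = g,
                   trait_category = catalog$trait_category[i],
                   rank = row$rank,
                   rank_percentile = row$rank_percentile,
                   n_ranked = nrow(ranking))
  })
  by_category <- per_gene |>
    dplyr::summarise(n = dplyr::n(),
                     mean_percentile = mean(.data$rank_percentile),
                     median_percentile = stats::median(.data$rank_percentile),
                     .by = "trait_category")
  structure(list(per_gene = per_gene, by_category = by_category,
                 flank = flank, config = config),
            class = "qtg_trait_report")
}

#' @export
print.qtg_trait_report <- function(x, ...) {
  cat("<qtg_trait_report>", nrow(x$per_gene), "causal genes,",
      x$flank, "flanking genes each\n")
  print(x$by_category, ...)
  invisible(x)
}
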