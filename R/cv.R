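#' Configure the extended cross-validation regime
#'
#' Known causal genes are few and unlabeled genes vastly outnumber them, so a
#' single 5-fold split wastes information and a single negative draw is
#' arbitrary. The extended regime iterates both: the positives are randomly
#' re-split into training and testing sets in a `(folds-1):1` ratio `R` times,
#' and for each re-split the negatives are re-drawn from the rest of the
#' genome `S` times, giving `R * S` train/test iterations. Training sets carry
#' `train_neg_ratio` negatives per positive (20 performed best for the
#' Arabidopsis-scale problem, 5 for rice); test sets use `test_neg_ratio`
#' (default 200) to mimic the causal:non-causal ratio inside a real QTL.
#'
#' @param folds Cross-validation folds; positives are split
#'   `(folds-1):1` train:test.
#' @param positive_resplits `R`, number of positive re-splits.
#' @param negative_resamples `S`, negative redraws per re-split.
#' @param train_neg_ratio Training negatives per training positive.
#' @param test_neg_ratio Test negatives per test positive.
#' @param classifier A [classifier_spec()].
#' @param decision_threshold Predicted-probability cutoff for calling a gene
#'   "causal" when pooling the confusion matrix.
#' @param master_seed Integer seed; every iteration's seed derives from it, so
#'   a whole run is reproducible and any single iteration re-runnable.
#' @return A `qtg_cv_config` list.
#' @export
cv_config <- function(folds = 5, positive_resplits = 50, negative_resamples = 50,
                      train_neg_ratio = 20, test_neg_ratio = 200,
                      classifier = classifier_spec(),
                      decision_threshold = 0.5, master_seed = 1) {
  stopifnot(folds >= 2, positive_resplits >= 1, negative_resamples >= 1,
            train_neg_ratio >= 1, test_neg_ratio >= 1,
            decision_threshold > 0, decision_threshold < 1)
  structure(list(folds = as.integer(folds),
                 positive_resplits = as.integer(positive_resplits),
                 negative_resamples = as.integer(negative_resamples),
                 train_neg_ratio = train_neg_ratio,
                 test_neg_ratio = test_neg_ratio,
                 classifier = classifier,
                 decision_threshold = decision_threshold,
                 master_seed = as.integer(master_seed)),
            class = "qtg_cv_config")
}

# Deterministic per-iteration seed below 2^31; exact in double arithmetic.
derive_seed <- function(master, a = 0L, b = 0L, c = 0L) {
  m <- 2147483647
  s <- (as.numeric(master) %% m)
  s <- (s * 48271 + as.numeric(a) * 16807 + 1) %% m
  s <- (s * 48271 + as.numeric(b) * 69621 + 1) %% m
  s <- (s * 48271 + as.numeric(c) * 16807 + 1) %% m
  as.integer(s)
}

#' Probability that a positive and a negative co-occur during cross-validation
#'
#' Each iteration draws `n` of the `N` candidate negatives without
#' replacement, so a given negative appears with probability `n/N`; over
#' `R * C * S` independent iteration-slots (R positive re-splits, C folds
#' holding a given positive, S negative redraws) the chance it ever co-occurs
#' with a given positive is `1 - ((N - n)/N)^(R*C*S)`. Used to check that the
#' iteration counts are large enough that every positive effectively meets
#' every negative.
#'
#' @param N Total candidate negatives in the genome.
#' @param n Negatives drawn per iteration.
#' @param R,C,S Positive re-splits, folds containing the positive (4 for
#'   training sets, 1 for test sets), negative redraws.
#' @return Probability in \[0, 1\].
#' @export
#' @examples
#' cooccurrence_probability(N = 27000, n = 960, R = 50, C = 4, S = 50)
cooccurrence_probability <- function(N, n, R = 1, C = 1, S = 1) {
  stopifnot(N >= 1, R >= 1, C >= 1, S >= 1)
  if (n > N || n < 0) stop("n must satisfy 0 <= n <= N")
  1 - ((N - n) / N)^(R * C * S)
}

#' Draw one train/test split of the extended cross-validation
#'
#' Positives are re-split `(folds-1):1` (re-split index `r`); training
#' negatives are drawn uniformly without replacement from the genome minus
#' *all* positives, `train_neg_ratio` per training positive (resample index
#' `s`); test negatives are drawn from the genome minus all positives minus
#' that iteration's training negatives, so train and test negatives never
#' collide within an iteration. The split is a pure function of
#' `(master_seed, r, s)`: the positive re-split depends on `(master_seed, r)`
#' only.
#'
#' @param positives Character vector of positive gene ids.
#' @param genome_gene_ids All gene ids in the genome.
#' @param config A [cv_config()].
#' @param r,s Re-split and resample indices (1-based).
#' @return List with tibbles `train` and `test`, each with columns `gene_id`,
#'   `label` (1 = positive).
#' @export
sample_split <- function(positives, genome_gene_ids, config, r, s) {
  positives <- as.character(positives)
  stopifnot(all(positives %in% genome_gene_ids))
  npos <- length(positives)
  n_test_pos <- max(1L, round(npos / config$folds))
  if (npos - n_test_pos < 1) stop("too few positives to split ", config$folds, "-fold")

  shuffled <- withr::with_seed(
    derive_seed(config$master_seed, r, 0L, 1L),
    sample(positives)
  )
  test_pos <- shuffled[seq_len(n_test_pos)]
  train_pos <- shuffled[-seq_len(n_test_pos)]

  pool <- setdiff(genome_gene_ids, positives)
  n_train_neg <- length(train_pos) * config$train_neg_ratio
  n_test_neg <- n_test_pos * config$test_neg_ratio
  if (length(pool) < n_train_neg + n_test_neg) {
    stop(sprintf("insufficient negatives: need %d, pool has %d",
                 n_train_neg + n_test_neg, length(pool)))
  }
  negs <- withr::with_seed(
    derive_seed(config$master_seed, r, s, 2L),
    sample(pool, n_train_neg + n_test_neg)
  )
  train_neg <- negs[seq_len(n_train_neg)]
  test_neg <- negs[n_train_neg + seq_len(n_test_neg)]

  list(
    train = tibble::tibble(gene_id = c(train_pos, train_neg),
                           label = rep(c(1L, 0L), c(length(train_pos), n_train_neg))),
    test = tibble::tibble(gene_id = c(test_pos, test_neg),
                          label = rep(c(1L, 0L), c(n_test_pos, n_test_neg)))
  )
}

#' AUC-ROC by the rank statistic
#'
#' Mann-Whitney form: with midranks for ties,
#' `AUC = (sum of positive ranks - npos(npos+1)/2) / (npos * nneg)`.
#' Identical to the trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels 0/1 labels.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  pos <- labels == 1
  npos <- sum(pos); nneg <- sum(!pos)
  if (npos == 0 || nneg == 0) stop("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# Empirical ROC as (fpr, tpr) step-curve points including (0,0) and (1,1).
roc_points <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  tp <- cumsum(lab == 1); fp <- cumsum(lab == 0)
  # collapse tied scores to the last point of each tie group
  keep <- c(diff(scores[o]) != 0, TRUE)
  tibble::tibble(
    fpr = c(0, fp[keep] / max(sum(labels == 0), 1)),
    tpr = c(0, tp[keep] / max(sum(labels == 1), 1))
  )
}

# TPR at fixed FPR grid (step-function interpolation, conservative).
tpr_at_grid <- function(scores, labels, grid) {
  rp <- roc_points(scores, labels)
  stats::approx(rp$fpr, rp$tpr, xout = grid, method = "linear",
                ties = max, rule = 2)$y
}

iterate_cv <- function(table, positives, config, per_iteration) {
  m <- feature_matrix(table)
  genome <- table$gene_id
  out <- list()
  for (r in seq_len(config$positive_resplits)) {
    for (s in seq_len(config$negative_resamples)) {
      split <- sample_split(positives, genome, config, r, s)
      if (length(unique(split$test$label)) < 2) {
        warning(sprintf("iteration (r=%d, s=%d): single-class test split, skipped", r, s))
        next
      }
      seed <- derive_seed(config$master_seed, r, s, 3L)
      out[[length(out) + 1L]] <- per_iteration(
        r = r, s = s,
        xtr = m[split$train$gene_id, , drop = FALSE], ytr = split$train$label,
        xte = m[split$test$gene_id, , drop = FALSE], yte = split$test$label,
        seed = seed
      )
    }
  }
  out
}

#' Run the extended cross-validation
#'
#' For each of the `R * S` iterations, fits the classifier on the training
#' split, scores the test split, and records the rank-statistic AUC-ROC plus
#' the ROC curve evaluated on a fixed 101-point FPR grid. Iteration ROC curves
#' are averaged vertically (mean TPR per grid FPR); test predictions are
#' pooled into a single confusion matrix at the decision threshold.
#' Iterations whose test split ends up single-class are skipped with a warning
#' and excluded from the mean.
#'
#' @param table A feature table (see [as_feature_table()]).
#' @param positives Character vector of known causal gene ids (must appear in
#'   `table`).
#' @param config A [cv_config()].
#' @return A `qtg_cv` object: per-iteration AUCs, their mean and sd, the
#'   averaged ROC curve, the pooled confusion matrix and the config. Use
#'   [generics::tidy()] / [generics::glance()] or `autoplot()` on it.
#' @export
cross_validate <- function(table, positives, config = cv_config()) {
  stopifnot(all(positives %in% table$gene_id))
  grid <- seq(0, 1, by = 0.01)
  thr <- config$decision_threshold

  iters <- iterate_cv(table, positives, config, function(r, s, xtr, ytr, xte, yte, seed) {
    model <- fit_classifier(config$classifier, xtr, ytr, seed)
    p <- predict_prob(model, xte)
    list(r = r, s = s,
         auc = auc_rank(p, yte),
         tpr = tpr_at_grid(p, yte, grid),
         tp = sum(p >= thr & yte == 1), fp = sum(p >= thr & yte == 0),
         tn = sum(p < thr & yte == 0), fn = sum(p < thr & yte == 1))
  })
  if (!length(iters)) stop("all cross-validation iterations were degenerate")

  aucs <- tibble::tibble(
    r = vapply(iters, `[[`, integer(1), "r"),
    s = vapply(iters, `[[`, integer(1), "s"),
    auc = vapply(iters, `[[`, numeric(1), "auc")
  )
  tpr_mat <- do.call(rbind, lapply(iters, `[[`, "tpr"))
  confusion <- c(
    tp = sum(vapply(iters, `[[`, numeric(1), "tp")),
    fp = sum(vapply(iters, `[[`, numeric(1), "fp")),
    tn = sum(vapply(iters, `[[`, numeric(1), "tn")),
    fn = sum(vapply(iters, `[[`, numeric(1), "fn"))
  )
  structure(list(
    auc = aucs,
    mean_auc = mean(aucs$auc),
    sd_auc = stats::sd(aucs$auc),
    roc = tibble::tibble(fpr = grid, tpr = colMeans(tpr_mat)),
    confusion = confusion,
    n_iterations = nrow(aucs),
    n_skipped = config$positive_resplits * config$negative_resamples - nrow(aucs),
    config = config
  ), class = "qtg_cv")
}

#' @export
print.qtg_cv <- function(x, ...) {
  cat(sprintf("<qtg_cv> %d iterations: mean AUC-ROC %.3f (sd %.3f)\n",
              x$n_iterations, x$mean_auc, x$sd_auc))
  cat("confusion (pooled): TP", x$confusion["tp"], "FP", x$confusion["fp"],
      "TN", x$confusion["tn"], "FN", x$confusion["fn"], "\n")
  invisible(x)
}

#' Leave-one-out feature importance
#'
#' A random forest exploits feature interactions, so single-feature enrichment
#' understates importance; instead, each feature's contribution is measured as
#' the drop in AUC-ROC when it is withheld. For every cross-validation
#' iteration the full model and each leave-one-out model are fitted on the
#' *same* train/test split, and `delta AUC = full - leave-one-out` is averaged
#' per feature across iterations. A positive mean delta marks a feature the
#' model needs; near-zero deltas mark redundant or uninformative features
#' (note a duplicated informative column shows near-zero delta because its
#' copy compensates).
#'
#' @inheritParams cross_validate
#' @return A `qtg_importance` object wrapping a tibble with columns `feature`,
#'   `mean_delta_auc`, `sd_delta_auc`, `n_iterations`.
#' @export
leave_one_out_importance <- function(table, positives, config = cv_config()) {
  feats <- setdiff(names(table), "gene_id")
  if (length(feats) < 2) stop("leave-one-out importance needs at least 2 features")

  iters <- iterate_cv(table, positives, config, function(r, s, xtr, ytr, xte, yte, seed) {
    full <- auc_rank(predict_prob(fit_classifier(config$classifier, xtr, ytr, seed), xte), yte)
    loo <- vapply(feats, function(f) {
      keep <- setdiff(feats, f)
      m <- fit_classifier(config$classifier, xtr[, keep, drop = FALSE], ytr, seed)
      auc_rank(predict_prob(m, xte[, keep, drop = FALSE]), yte)
    }, numeric(1))
    full - loo
  })
  if (!length(iters)) stop("all cross-validation iterations were degenerate")
  d <- do.call(rbind, iters)
  structure(list(
    importance = tibble::tibble(
      feature = feats,
      mean_delta_auc = colMeans(d),
      sd_delta_auc = apply(d, 2, stats::sd),
      n_iterations = nrow(d)
    ) |> dplyr::arrange(dplyr::desc(.data$mean_delta_auc)),
    config = config
  ), class = "qtg_importance")
}

#' @export
print.qtg_importance <- function(x, ...) {
  cat("<qtg_importance> mean delta-AUC over", x$importance$n_iterations[1],
      "iterations\n")
  print(x$importance, ...)
  invisible(x)
}

#' Enrichment of a feature in causal genes relative to the genome
#'
#' The ratio of the feature's mean among known causal genes to its mean over
#' all genes. For a binary feature this is the frequency ratio (e.g. causal
#' genes being transporters 2x as often as the genome background).
#'
#' @param table A feature table.
#' @param positives Causal gene ids.
#' @param feature_name One feature name, or `NULL` for all features.
#' @return Tibble with columns `feature`, `positive_mean`, `genome_mean`,
#'   `enrichment_ratio`.
#' @export
enrichment_ratio <- function(table, positives, feature_name = NULL) {
  feats <- feature_name %||% setdiff(names(table), "gene_id")
  missing <- setdiff(feats, names(table))
  if (length(missing)) stop("unknown feature(s): ", paste(missing, collapse = ", "))
  stopifnot(all(positives %in% table$gene_id))
  pos <- table[table$gene_id %in% positives, ]
  purrr::map_dfr(feats, function(f) {
    gm <- mean(table[[f]])
    if (gm == 0) stop("genome mean of '", f, "' is zero; ratio undefined")
    tibble::tibble(feature = f,
                   positive_mean = mean(pos[[f]]),
                   genome_mean = gm,
                   enrichment_ratio = mean(pos[[f]]) / gm)
  })
}
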