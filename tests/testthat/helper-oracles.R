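# Independent oracles used to cross-check the implementation. These are
# deliberately naive (loops, enumeration, dense matrices) and share no code
# with the functions they verify.

# Trapezoidal area under the empirical ROC curve, built point by point.
trapezoid_auc <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  sc <- scores[o]
  tp <- cumsum(lab == 1)
  fp <- cumsum(lab == 0)
  keep <- c(diff(sc) != 0, TRUE)   # collapse tied scores
  tpr <- c(0, tp[keep] / sum(labels == 1))
  fpr <- c(0, fp[keep] / sum(labels == 0))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# O(n) scan over every gene for interval membership.
brute_genes_in_qtl <- function(annotation, region) {
  hit <- character(0)
  for (i in seq_len(nrow(annotation))) {
    if (annotation$chromosome[i] == region$chromosome &&
        annotation$start[i] <= region$right_marker_pos &&
        annotation$end[i] >= region$left_marker_pos) {
      hit <- c(hit, annotation$gene_id[i])
    }
  }
  ord <- order(annotation$start[match(hit, annotation$gene_id)])
  hit[ord]
}

# P(at least K successes in N Bernoulli(p) trials) by enumerating all 2^N
# outcomes.
enumerate_at_least_k <- function(p, N, K) {
  outcomes <- as.matrix(expand.grid(rep(list(0:1), N)))
  probs <- apply(outcomes, 1, function(o) prod(ifelse(o == 1, p, 1 - p)))
  sum(probs[rowSums(outcomes) >= K])
}

# Node weight by dense adjacency row sums.
adjacency_row_sums <- function(edges, gene_ids) {
  n <- length(gene_ids)
  A <- matrix(0, n, n, dimnames = list(gene_ids, gene_ids))
  for (i in seq_len(nrow(edges))) {
    a <- edges$gene_a[i]; b <- edges$gene_b[i]; w <- edges$weight[i]
    if (a == b) {
      A[a, b] <- A[a, b] + w
    } else {
      A[a, b] <- A[a, b] + w
      A[b, a] <- A[b, a] + w
    }
  }
  rowSums(A)
}

# A small planted-signal fixture spec that keeps model fits fast.
small_fixture_spec <- function(seed = 1, ...) {
  fixture_spec(n_genes = 400, n_chromosomes = 2, n_causal = 10,
               qtl_width = 20, seed = seed, ...)
}

# A fast CV configuration for unit tests (not the production regime).
fast_cv <- function(..., R = 3, S = 2, seed = 1) {
  cv_config(positive_resplits = R, negative_resamples = S,
            train_neg_ratio = 5, test_neg_ratio = 10,
            classifier = classifier_spec(n_trees = 50, max_features = 4),
            master_seed = seed, ...)
}

# Random gene-id universe helper.
gene_universe <- function(n) sprintf("g%04d", seq_len(n))
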