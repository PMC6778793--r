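test_that("multi-QTL recall probability matches enumeration and behaves at bounds", {
  # exhaustive 2^N enumeration oracle on random instances
  withr::with_seed(19, {
    for (i in 1:40) {
      N <- sample(1:12, 1)
      K <- sample(1:N, 1)
      p <- runif(1)
      expect_equal(multi_qtl_recall_probability(p, N, K),
                   enumerate_at_least_k(p, N, K), tolerance = 1e-12)
    }
  })
  expect_equal(multi_qtl_recall_probability(0.4, 5, 0), 1.0)
  expect_equal(multi_qtl_recall_probability(0, 5, 1), 0.0)
  expect_error(multi_qtl_recall_probability(0.5, 3, 4), "exceed")

  # binomial terms normalise and the tail is monotone in p and K
  p <- 0.3; N <- 8
  expect_equal(sum(choose(N, 0:N) * p^(0:N) * (1 - p)^(N - (0:N))), 1)
  expect_equal(multi_qtl_recall_probability(p, N, 1),
               1 - stats::pbinom(0, N, p), tolerance = 1e-12)
  for (K in 1:(N - 1)) {
    expect_gte(multi_qtl_recall_probability(p, N, K),
               multi_qtl_recall_probability(p, N, K + 1))
    expect_lte(multi_qtl_recall_probability(p - 0.1, N, K),
               multi_qtl_recall_probability(p, N, K))
  }
})

test_that("recall at a cutoff counts percentiles strictly below it", {
  # 7 of 11 causal genes inside the top 20%
  pct <- c(2, 5, 8, 11, 15, 17, 19.9, 20, 45, 60, 80)
  expect_equal(recall_at_cutoff(pct, 20), 7 / 11)
  expect_equal(recall_at_cutoff(pct, 100), 1.0)
  expect_equal(recall_at_cutoff(tibble::tibble(rank_percentile = pct), 20), 7 / 11)
  expect_error(recall_at_cutoff(numeric(0), 20), "empty")
  withr::with_seed(2, {
    x <- runif(50, 0, 100)
    cut <- runif(1, 1, 99)
    expect_equal(recall_at_cutoff(x, cut), sum(x < cut) / 50)
  })
})

test_that("ensembles are reproducible and batch-invariant under the seed schedule", {
  fx <- generate_fixture(small_fixture_spec(seed = 10))
  cfg <- ensemble_config(n_models = 12, train_neg_ratio = 5,
                         classifier = classifier_spec(n_trees = 30, max_features = 4),
                         master_seed = 42)
  e1 <- train_ensemble(fx$feature_table, fx$catalog$gene_id, cfg)
  e2 <- train_ensemble(fx$feature_table, fx$catalog$gene_id, cfg)
  genes <- genes_in_qtl(fx$annotation, fx$qtl[1, ])
  f1 <- prediction_frequency(e1, fx$feature_table, genes)
  f2 <- prediction_frequency(e2, fx$feature_table, genes)
  expect_identical(f1, f2)

  # a single-model ensemble is just one resampled fit
  cfg1 <- ensemble_config(n_models = 1, train_neg_ratio = 5,
                          classifier = classifier_spec(n_trees = 30, max_features = 4),
                          master_seed = 42)
  e3 <- train_ensemble(fx$feature_table, fx$catalog$gene_id, cfg1)
  f3 <- prediction_frequency(e3, fx$feature_table, genes)
  expect_true(all(f3 %in% c(0, 1)))
  # model 1 of the 12-model ensemble votes identically (same derived seed)
  votes1 <- as.numeric(predict_prob(e1$models[[1]],
                                    qtgrank:::feature_matrix(fx$feature_table)[genes, ]) >= 0.5)
  expect_equal(unname(f3), votes1)

  expect_error(train_ensemble(fx$feature_table, fx$feature_table$gene_id[1:350],
                              ensemble_config(n_models = 1, train_neg_ratio = 20)),
               "insufficient")
})

test_that("genome-scale ensemble iteration counts cover every gene with >99% probability", {
  # 5,000 resampled draws of 1,200 negatives from a 27,000-gene pool
  p_gene <- 1 - (1 - 1200 / 27000)^5000
  expect_gte(p_gene, 0.99)
  expect_equal(p_gene, cooccurrence_probability(27000, 1200, R = 5000), tolerance = 1e-12)
})

test_that("QTL ranking orders by frequency with strictly-higher percentiles", {
  fx <- generate_fixture(small_fixture_spec(seed = 20))
  cfg <- ensemble_config(n_models = 25, train_neg_ratio = 5,
                         classifier = classifier_spec(n_trees = 30, max_features = 4),
                         master_seed = 1)
  ens <- train_ensemble(fx$feature_table, fx$catalog$gene_id, cfg)
  genes <- genes_in_qtl(fx$annotation, fx$qtl[2, ])
  rk <- rank_qtl_genes(ens, fx$feature_table, genes)
  expect_setequal(rk$gene_id, genes)
  expect_equal(sort(rk$rank), seq_along(genes))
  expect_true(all(diff(rk$prediction_frequency) <= 0))
  expect_equal(rk$rank_percentile[1], 0)
  expect_true(all(rk$rank_percentile >= 0 & rk$rank_percentile < 100))
  # percentile = share of genes with strictly higher frequency; ties share it
  for (i in seq_len(nrow(rk))) {
    expect_equal(rk$rank_percentile[i],
                 100 * sum(rk$prediction_frequency > rk$prediction_frequency[i]) /
                   nrow(rk))
  }
  # invariant to input order
  rk2 <- rank_qtl_genes(ens, fx$feature_table, rev(genes))
  expect_equal(rk2, rk)
  # precomputed frequencies give the same ranking
  fr <- prediction_frequency(ens, fx$feature_table, genes)
  expect_equal(rank_qtl_genes(ens, fx$feature_table, genes, frequencies = fr), rk)

  # degenerate tie: identical feature rows -> equal frequency, all percentile 0
  ids <- gene_universe(30)
  flat <- as_feature_table(tibble::tibble(gene_id = ids,
                                          a = rep(1, 30), b = rep(0.5, 30)))
  pos <- ids[1:5]
  ens_flat <- train_ensemble(flat, pos,
                             ensemble_config(n_models = 5, train_neg_ratio = 2,
                                             classifier = classifier_spec(n_trees = 10, max_features = 2),
                                             master_seed = 3))
  rk_flat <- rank_qtl_genes(ens_flat, flat, ids[6:20])
  expect_equal(length(unique(rk_flat$prediction_frequency)), 1)
  expect_true(all(rk_flat$rank_percentile == 0))

  # genes missing from the table are flagged and ranked last
  expect_warning(rk3 <- rank_qtl_genes(ens, fx$feature_table, c(genes, "ghost")),
                 "ghost")
  expect_true(rk3$missing_features[rk3$gene_id == "ghost"])
  expect_equal(rk3$rank[rk3$gene_id == "ghost"], nrow(rk3))
})

test_that("trait-category rank test holds each catalog gene out exactly once", {
  fx <- generate_fixture(small_fixture_spec(seed = 30))
  cfg <- ensemble_config(n_models = 10, train_neg_ratio = 5,
                         classifier = classifier_spec(n_trees = 25, max_features = 4),
                         master_seed = 2)
  rep <- trait_category_rank_test(fx$feature_table, fx$catalog, fx$annotation,
                                  cfg, flank = 30)
  expect_equal(nrow(rep$per_gene), nrow(fx$catalog))
  expect_equal(sort(rep$per_gene$gene_id), sort(fx$catalog$gene_id))
  expect_true(all(rep$per_gene$rank_percentile >= 0 & rep$per_gene$rank_percentile < 100))
  expect_equal(rep$per_gene$n_ranked, rep(31, nrow(fx$catalog)))
  expect_setequal(rep$by_category$trait_category, unique(fx$catalog$trait_category))

  # a 1-gene catalog leaves no positives after holdout
  expect_error(
    trait_category_rank_test(fx$feature_table, fx$catalog[1, ], fx$annotation, cfg),
    "at least 2")
  # catalog gene missing from the annotation
  bad <- fx$catalog
  bad$gene_id[1] <- "ghost"
  tab2 <- fx$feature_table
  tab2$gene_id[tab2$gene_id == fx$catalog$gene_id[1]] <- "ghost"
  expect_error(
    trait_category_rank_test(as_feature_table(tibble::as_tibble(tab2)), bad,
                             fx$annotation, cfg),
    "absent from annotation")
})

test_that("categories with stronger planted effects rank better", {
  # abiotic-stress causal genes get amplified effects, development attenuated;
  # pooled over seeds the abiotic percentiles should be better (smaller)
  pooled <- purrr::map_dfr(1:6, function(seed) {
    fx <- generate_fixture(small_fixture_spec(
      seed = seed,
      trait_props = c("development" = 0.5, "abiotic stress" = 0.5,
                      "biotic stress" = 0, "other" = 0),
      category_effects = c("abiotic stress" = 1.6, "development" = 0.4)
    ))
    cfg <- ensemble_config(n_models = 12, train_neg_ratio = 5,
                           classifier = classifier_spec(n_trees = 25, max_features = 4),
                           master_seed = seed)
    tidy(trait_category_rank_test(fx$feature_table, fx$catalog, fx$annotation,
                                  cfg, flank = 30))
  })
  means <- pooled |>
    dplyr::summarise(m = mean(rank_percentile), .by = trait_category)
  expect_lt(means$m[means$trait_category == "abiotic stress"],
            means$m[means$trait_category == "development"])
})
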