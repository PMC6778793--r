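test_that("co-occurrence probability matches closed form, Monte Carlo and bounds", {
  # single draw: P = n/N
  expect_equal(cooccurrence_probability(10, 3), 0.3)
  expect_equal(cooccurrence_probability(10, 10, R = 7, C = 4, S = 3), 1.0)
  expect_error(cooccurrence_probability(10, 11), "0 <= n <= N")

  # Monte-Carlo oracle on a small instance, within 3 standard errors
  withr::with_seed(404, {
    nrep <- 20000
    hit <- replicate(nrep, 1 %in% sample.int(10, 3))
    se <- sqrt(0.3 * 0.7 / nrep)
    expect_lt(abs(mean(hit) - cooccurrence_probability(10, 3)), 3 * se)
  })

  # monotone non-decreasing in n, R, C, S
  base <- cooccurrence_probability(100, 10, R = 2, C = 2, S = 2)
  expect_gte(cooccurrence_probability(100, 20, R = 2, C = 2, S = 2), base)
  expect_gte(cooccurrence_probability(100, 10, R = 3, C = 2, S = 2), base)
  expect_gte(cooccurrence_probability(100, 10, R = 2, C = 4, S = 2), base)
  expect_gte(cooccurrence_probability(100, 10, R = 2, C = 2, S = 5), base)
})

test_that("split sizes follow the 4:1 re-split and the negative ratios", {
  genome <- gene_universe(5000)
  pos <- genome[1:60]
  cfg <- cv_config(train_neg_ratio = 20, test_neg_ratio = 200, master_seed = 9)
  sp <- sample_split(pos, genome, cfg, r = 1, s = 1)
  expect_equal(sum(sp$train$label == 1), 48)
  expect_equal(sum(sp$train$label == 0), 960)
  expect_equal(sum(sp$test$label == 1), 12)
  expect_equal(sum(sp$test$label == 0), 2400)

  # identical (seed, r, s) gives identical splits
  sp2 <- sample_split(pos, genome, cfg, r = 1, s = 1)
  expect_identical(sp, sp2)
  # different s re-draws negatives but keeps the positive re-split
  sp3 <- sample_split(pos, genome, cfg, r = 1, s = 2)
  expect_identical(sp3$train$gene_id[sp3$train$label == 1],
                   sp$train$gene_id[sp$train$label == 1])
  expect_false(identical(sp3$train$gene_id[sp3$train$label == 0],
                         sp$train$gene_id[sp$train$label == 0]))

  expect_error(sample_split(pos, genome[1:100], cfg, 1, 1), "insufficient negatives")
})

test_that("splits never leak: negatives exclude positives and train/test negatives are disjoint", {
  withr::with_seed(12, {
    for (i in 1:100) {
      n_genome <- sample(300:800, 1)
      genome <- gene_universe(n_genome)
      pos <- sample(genome, sample(10:25, 1))
      cfg <- cv_config(train_neg_ratio = sample(2:6, 1),
                       test_neg_ratio = sample(5:15, 1),
                       master_seed = i)
      sp <- sample_split(pos, genome, cfg, r = sample(1:50, 1), s = sample(1:50, 1))
      train_neg <- sp$train$gene_id[sp$train$label == 0]
      test_neg <- sp$test$gene_id[sp$test$label == 0]
      expect_length(intersect(train_neg, pos), 0)
      expect_length(intersect(test_neg, pos), 0)
      expect_length(intersect(train_neg, test_neg), 0)
      expect_length(intersect(sp$train$gene_id[sp$train$label == 1],
                              sp$test$gene_id[sp$test$label == 1]), 0)
    }
  })
})

test_that("rank-statistic AUC equals the trapezoidal ROC area, with and without ties", {
  withr::with_seed(31, {
    for (i in 1:100) {
      n <- sample(10:200, 1)
      labels <- rbinom(n, 1, 0.4)
      if (length(unique(labels)) < 2) next
      scores <- if (i %% 2 == 0) rnorm(n) else sample(seq(0, 1, 0.1), n, replace = TRUE)
      expect_equal(auc_rank(scores, labels), trapezoid_auc(scores, labels),
                   tolerance = 1e-12)
    }
  })
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(8, {
    labels <- rbinom(80, 1, 0.5)
    scores <- rnorm(80) + labels
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc_rank(scores, labels), ref, tolerance = 1e-12)
  })
})

test_that("a perfectly separating feature yields near-perfect cross-validated AUC", {
  withr::with_seed(55, {
    genome <- gene_universe(400)
    pos <- sample(genome, 20)
    tab <- as_feature_table(tibble::tibble(
      gene_id = genome,
      oracle_flag = as.numeric(genome %in% pos),
      noise = rnorm(400)
    ))
    res <- cross_validate(tab, pos, fast_cv(seed = 2))
    expect_gte(res$mean_auc, 0.99)
    expect_true(all(res$auc$auc >= 0 & res$auc$auc <= 1))
    # averaged ROC is monotone on the grid
    expect_true(all(diff(res$roc$tpr) >= -1e-12))
    # confusion counts account for every test prediction
    n_test <- sum(res$confusion)
    expect_equal(n_test, res$n_iterations * (4 + 4 * 10))
  })
})

test_that("cross-validation is bit-reproducible from the master seed", {
  fx <- generate_fixture(small_fixture_spec(seed = 4))
  r1 <- cross_validate(fx$feature_table, fx$catalog$gene_id, fast_cv(R = 2, S = 2, seed = 77))
  r2 <- cross_validate(fx$feature_table, fx$catalog$gene_id, fast_cv(R = 2, S = 2, seed = 77))
  expect_identical(r1$auc, r2$auc)
  expect_identical(r1$roc, r2$roc)
  expect_identical(r1$confusion, r2$confusion)
})

test_that("leave-one-out importance finds planted signal, redundancy and constants", {
  withr::with_seed(66, {
    genome <- gene_universe(500)
    pos <- sample(genome, 25)
    strong <- as.numeric(genome %in% pos) * 0.8 + rnorm(500, sd = 0.4)
    tab <- as_feature_table(tibble::tibble(
      gene_id = genome,
      signal = strong,
      dup_a = rnorm(500), # redundant pair below
      noise1 = rnorm(500),
      noise2 = rbinom(500, 1, 0.3)
    ))
    imp <- leave_one_out_importance(tab, pos, fast_cv(R = 4, S = 3, seed = 5))
    d <- tidy(imp)
    expect_gt(d$mean_delta_auc[d$feature == "signal"], 0)
    expect_lt(max(abs(d$mean_delta_auc[d$feature %in% c("noise1", "noise2")])), 0.03)

    # duplicated informative columns mask each other
    tab2 <- as_feature_table(tibble::tibble(
      gene_id = genome, sig_a = strong, sig_b = strong, noise = rnorm(500)
    ))
    imp2 <- tidy(leave_one_out_importance(tab2, pos, fast_cv(R = 4, S = 3, seed = 6)))
    expect_lt(abs(imp2$mean_delta_auc[imp2$feature == "sig_a"]), 0.03)
    expect_lt(abs(imp2$mean_delta_auc[imp2$feature == "sig_b"]), 0.03)

    # constant column contributes nothing
    tab3 <- as_feature_table(tibble::tibble(
      gene_id = genome, sig = strong, konst = rep(1, 500)
    ))
    imp3 <- tidy(leave_one_out_importance(tab3, pos, fast_cv(R = 3, S = 2, seed = 7)))
    expect_lt(abs(imp3$mean_delta_auc[imp3$feature == "konst"]), 0.02)

    expect_error(
      leave_one_out_importance(
        as_feature_table(tibble::tibble(gene_id = genome, only = strong)),
        pos, fast_cv()),
      "at least 2 features")
  })
})

test_that("enrichment ratios are positive-set over genome means", {
  tab <- as_feature_table(tibble::tibble(
    gene_id = gene_universe(10),
    flag = c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0), # 0.2 in positives, 0.1 genome-wide? no:
    same = rep(2, 10)
  ))
  # construct exactly: frequency 0.2 among 5 positives, 0.1 among all 10
  tab$flag <- c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0)
  pos <- gene_universe(10)[1:5]
  er <- enrichment_ratio(tab, pos, "flag")
  expect_equal(er$enrichment_ratio, (1 / 5) / (1 / 10))
  expect_equal(enrichment_ratio(tab, pos, "same")$enrichment_ratio, 1)
  expect_error(enrichment_ratio(
    as_feature_table(tibble::tibble(gene_id = c("a", "b"), z = c(0, 0))),
    "a", "z"), "zero")

  # two-pass mean oracle on random tables
  withr::with_seed(14, {
    ids <- gene_universe(50)
    t2 <- as_feature_table(tibble::tibble(gene_id = ids, v = rexp(50)))
    p2 <- sample(ids, 12)
    er2 <- enrichment_ratio(t2, p2, "v")
    expect_equal(er2$enrichment_ratio,
                 mean(t2$v[t2$gene_id %in% p2]) / mean(t2$v))
  })
})
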