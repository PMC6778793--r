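#' Species profiles
#'
#' Bundled defaults for the two genomes the method was developed on. The only
#' profile-dependent parameter is the training positives:negatives ratio,
#' selected by cross-validation: 1:20 for an Arabidopsis-scale problem and 1:5
#' for rice.
#'
#' @param name `"arabidopsis"` or `"rice"`.
#' @return A list with `name` and `train_neg_ratio`.
#' @export
species_profile <- function(name = c("arabidopsis", "rice")) {
  name <- match.arg(name)
  list(name = name, train_neg_ratio = if (name == "arabidopsis") 20 else 5)
}

run_config_defaults <- function() {
  list(species_profile = "arabidopsis", folds = 5,
       positive_resplits = 50, negative_resamples = 50,
       train_neg_ratio = NULL, test_neg_ratio = 200,
       n_trees = 100, max_features = 9, classifier = "random_forest",
       decision_threshold = 0.5, n_models = 5000, flank = 200, seed = 1)
}

#' Load and resolve a run configuration
#'
#' Reads an optional YAML/JSON file, overlays explicit flag-style overrides
#' (overrides win, with a note), applies the species profile's negative ratio
#' where none was given, and fills remaining defaults. Unknown keys are an
#' error listing the valid ones.
#'
#' @param path Optional path to a YAML or JSON configuration file.
#' @param overrides Named list of values that take precedence over the file.
#' @return A named list with all configuration keys resolved. Feed it to
#'   [cv_config()] / [ensemble_config()] via the corresponding fields.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  defaults <- run_config_defaults()
  file_cfg <- list()
  if (!is.null(path)) {
    file_cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (is.null(file_cfg)) file_cfg <- list()
  }
  for (cfg in list(file_cfg, overrides)) {
    bad <- setdiff(names(cfg), names(defaults))
    if (length(bad)) {
      stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
           "; valid keys: ", paste(names(defaults), collapse = ", "))
    }
  }
  clash <- intersect(names(file_cfg), names(overrides))
  clash <- clash[!vapply(clash, function(k)
    identical(file_cfg[[k]], overrides[[k]]), logical(1))]
  if (length(clash)) {
    message("flag overrides file value(s) for: ", paste(clash, collapse = ", "))
  }
  cfg <- utils::modifyList(utils::modifyList(defaults, file_cfg), overrides)
  if (is.null(cfg$train_neg_ratio)) {
    cfg$train_neg_ratio <- species_profile(cfg$species_profile)$train_neg_ratio
  }
  cfg
}

#' @rdname load_run_config
#' @param cfg A resolved configuration list.
#' @export
config_as_cv <- function(cfg) {
  cv_config(folds = cfg$folds, positive_resplits = cfg$positive_resplits,
            negative_resamples = cfg$negative_resamples,
            train_neg_ratio = cfg$train_neg_ratio,
            test_neg_ratio = cfg$test_neg_ratio,
            classifier = classifier_spec(cfg$classifier, cfg$n_trees, cfg$max_features),
            decision_threshold = cfg$decision_threshold,
            master_seed = cfg$seed)
}

#' @rdname load_run_config
#' @export
config_as_ensemble <- function(cfg) {
  ensemble_config(n_models = cfg$n_models, train_neg_ratio = cfg$train_neg_ratio,
                  classifier = classifier_spec(cfg$classifier, cfg$n_trees, cfg$max_features),
                  decision_threshold = cfg$decision_threshold,
                  master_seed = cfg$seed)
}

#' Write a machine-readable run report
#'
#' Serialises a result object (cross-validation, importance, ranking or trait
#' report) to JSON, with companion TSV tables for the tabular parts. The
#' report records the package version and a hash of the configuration so runs
#' can be matched to their settings.
#'
#' @param result A `qtg_cv`, `qtg_importance`, `qtg_ranking` (or a named list
#'   of them per QTL), or `qtg_trait_report`.
#' @param out_path Output JSON path; TSVs are written next to it.
#' @param seed Seed to record.
#' @return `out_path`, invisibly.
#' @export
run_report <- function(result, out_path, seed = NA) {
  meta <- list(
    package = "qtgrank",
    version = as.character(utils::packageVersion("qtgrank")),
    seed = seed
  )
  stem <- sub("\\.json$", "", out_path)
  payload <- NULL
  if (inherits(result, "qtg_cv")) {
    payload <- list(mean_auc = result$mean_auc, sd_auc = result$sd_auc,
                    n_iterations = result$n_iterations,
                    n_skipped = result$n_skipped,
                    confusion = as.list(result$confusion),
                    auc = result$auc$auc,
                    roc = list(fpr = result$roc$fpr, tpr = result$roc$tpr))
    readr::write_tsv(result$auc, paste0(stem, "_auc.tsv"), progress = FALSE)
  } else if (inherits(result, "qtg_importance")) {
    payload <- list(importance = result$importance)
    readr::write_tsv(result$importance, paste0(stem, "_importance.tsv"),
                     progress = FALSE)
  } else if (inherits(result, "qtg_trait_report")) {
    payload <- list(per_gene = result$per_gene, by_category = result$by_category)
    readr::write_tsv(result$per_gene, paste0(stem, "_per_gene.tsv"),
                     progress = FALSE)
    readr::write_tsv(result$by_category, paste0(stem, "_by_category.tsv"),
                     progress = FALSE)
  } else if (inherits(result, "qtg_ranking") ||
             (is.list(result) && all(vapply(result, inherits, logical(1), "qtg_ranking")))) {
    tab <- ranking_table(result)
    payload <- list(ranking = tab)
    readr::write_tsv(tab, paste0(stem, "_ranked.tsv"), progress = FALSE)
  } else {
    stop("unsupported result type: ", paste(class(result), collapse = "/"))
  }
  jsonlite::write_json(c(meta, payload), out_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_path)
}

# Flatten one ranking or a named per-QTL list of rankings into the canonical
# (qtl_id, gene_id, frequency, rank, rank_percentile) table.
ranking_table <- function(result) {
  if (inherits(result, "qtg_ranking")) result <- list(`NA` = result)
  purrr::imap_dfr(result, function(rk, qtl_id) {
    tibble::tibble(qtl_id = qtl_id, gene_id = rk$gene_id,
                   frequency = rk$prediction_frequency,
                   rank = rk$rank, rank_percentile = rk$rank_percentile)
  })
}
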