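#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cross-validation result
#'
#' @param x A `qtg_cv` object.
#' @param ... Unused.
#' @return One row per iteration: `r`, `s`, `auc`.
#' @export
tidy.qtg_cv <- function(x, ...) x$auc

#' @rdname tidy.qtg_cv
#' @return For `glance()`: a one-row summary (mean/sd AUC, iteration counts,
#'   pooled confusion matrix).
#' @export
glance.qtg_cv <- function(x, ...) {
  tibble::tibble(mean_auc = x$mean_auc, sd_auc = x$sd_auc,
                 n_iterations = x$n_iterations, n_skipped = x$n_skipped,
                 tp = x$confusion[["tp"]], fp = x$confusion[["fp"]],
                 tn = x$confusion[["tn"]], fn = x$confusion[["fn"]])
}

#' Tidy a feature-importance result
#'
#' @param x A `qtg_importance` object.
#' @param ... Unused.
#' @return One row per feature: `feature`, `mean_delta_auc`, `sd_delta_auc`,
#'   `n_iterations`.
#' @export
tidy.qtg_importance <- function(x, ...) x$importance

#' Tidy a trait-category rank report
#'
#' @param x A `qtg_trait_report`.
#' @param ... Unused.
#' @return One row per tested causal gene.
#' @export
tidy.qtg_trait_report <- function(x, ...) x$per_gene

#' @rdname tidy.qtg_trait_report
#' @return For `glance()`: one row per trait category with mean/median rank
#'   percentile.
#' @export
glance.qtg_trait_report <- function(x, ...) x$by_category
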