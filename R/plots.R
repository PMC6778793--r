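#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the vertically averaged ROC curve of a cross-validation run
#'
#' @param object A `qtg_cv` result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qtg_cv <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("Mean AUC-ROC %.3f (sd %.3f, %d iterations)",
                      object$mean_auc, object$sd_auc, object$n_iterations)
    ) +
    ggplot2::theme_minimal()
}

#' Plot leave-one-out feature importance
#'
#' Bars show the mean drop in AUC-ROC when each feature is withheld; whiskers
#' are +/- one sd across iterations.
#'
#' @param object A `qtg_importance` result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qtg_importance <- function(object, ...) {
  d <- dplyr::mutate(object$importance,
                     feature = stats::reorder(.data$feature, .data$mean_delta_auc))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_delta_auc, y = .data$feature)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$mean_delta_auc - .data$sd_delta_auc,
                   xmax = .data$mean_delta_auc + .data$sd_delta_auc),
      height = 0.3, colour = "grey30"
    ) +
    ggplot2::labs(x = expression(Delta * "AUC-ROC when feature left out"),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a QTL gene ranking
#'
#' Prediction frequency by rank, with the rank-percentile cutoff of interest
#' marked.
#'
#' @param object A `qtg_ranking` tibble.
#' @param cutoff_percent Optional percentile cutoff to mark (default 20).
#' @param highlight Optional gene ids to label (e.g. a known causal gene).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qtg_ranking <- function(object, cutoff_percent = 20, highlight = NULL, ...) {
  d <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$rank,
                                       y = .data$prediction_frequency)) +
    ggplot2::geom_point(colour = "grey40") +
    ggplot2::geom_vline(xintercept = cutoff_percent / 100 * nrow(d),
                        linetype = "dashed", colour = "#d95f02") +
    ggplot2::labs(x = "Rank in QTL", y = "Ensemble prediction frequency") +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    hd <- d[d$gene_id %in% highlight, ]
    p <- p +
      ggplot2::geom_point(data = hd, colour = "#d95f02", size = 2.5) +
      ggplot2::geom_text(data = hd, ggplot2::aes(label = .data$gene_id),
                         vjust = -0.8, size = 3)
  }
  p
}

#' Plot rank percentiles by trait category
#'
#' One point per held-out causal gene; the dashed line marks the top-20%
#' cutoff typically used in practice.
#'
#' @param object A `qtg_trait_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qtg_trait_report <- function(object, ...) {
  ggplot2::ggplot(object$per_gene,
                  ggplot2::aes(x = .data$trait_category,
                               y = .data$rank_percentile)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, colour = "grey40") +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "#2c7fb8") +
    ggplot2::geom_hline(yintercept = 20, linetype = "dashed", colour = "#d95f02") +
    ggplot2::labs(x = NULL, y = "Rank percentile (0 = best)") +
    ggplot2::theme_minimal()
}
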