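#' Specify the base classifier
#'
#' The default base learner is a random forest with 100 trees, each tree
#' drawing at most 9 candidate features per split — the configuration selected
#' by cross-validation for this problem. The classifier is a pluggable seam: a
#' regularised logistic model is available as a cheap alternative for
#' experimentation, but the forest is what the ranking pipeline is built
#' around.
#'
#' @param kind `"random_forest"` or `"logistic"`.
#' @param n_trees Number of trees (random forest).
#' @param max_features Maximum features considered per split (random forest
#'   `mtry`); capped at the number of available features at fit time.
#' @return A `qtg_classifier_spec` list.
#' @export
classifier_spec <- function(kind = c("random_forest", "logistic"),
                            n_trees = 100, max_features = 9) {
  kind <- match.arg(kind)
  stopifnot(n_trees >= 1, max_features >= 1)
  structure(list(kind = kind, n_trees = as.integer(n_trees),
                 max_features = as.integer(max_features)),
            class = "qtg_classifier_spec")
}

# x: numeric matrix (rows = genes); y: 0/1 integer vector; seed: integer.
fit_classifier <- function(spec, x, y, seed) {
  stopifnot(inherits(spec, "qtg_classifier_spec"))
  if (spec$kind == "random_forest") {
    d <- as.data.frame(x)
    d$.label <- factor(y, levels = c(0, 1))
    fit <- ranger::ranger(
      dependent.variable.name = ".label", data = d,
      num.trees = spec$n_trees,
      mtry = min(spec$max_features, ncol(x)),
      probability = TRUE, seed = seed, num.threads = 1,
      verbose = FALSE
    )
    structure(list(spec = spec, fit = fit, features = colnames(x)),
              class = "qtg_classifier")
  } else {
    d <- as.data.frame(x)
    d$.label <- y
    fit <- withr::with_seed(seed, suppressWarnings(
      stats::glm(.label ~ ., data = d, family = stats::binomial())
    ))
    structure(list(spec = spec, fit = fit, features = colnames(x)),
              class = "qtg_classifier")
  }
}

# Probability of the positive class for each row of newx.
predict_prob <- function(model, newx) {
  stopifnot(inherits(model, "qtg_classifier"))
  newx <- newx[, model$features, drop = FALSE]
  if (model$spec$kind == "random_forest") {
    p <- stats::predict(model$fit, data = as.data.frame(newx),
                        num.threads = 1, verbose = FALSE)$predictions
    unname(p[, "1"])
  } else {
    unname(stats::predict(model$fit, newdata = as.data.frame(newx),
                          type = "response"))
  }
}
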