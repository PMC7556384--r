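#' Base-learner specification
#'
#' The ensemble is learner agnostic: any regressor/classifier pair satisfying
#' this contract can be plugged in. A learner spec bundles four functions:
#'
#' * `fit_regressor(x, y, seed)` — train a regressor on numeric matrix `x`
#'   and numeric response `y`; returns an opaque model.
#' * `predict_regressor(model, x)` — real-valued predictions, one per row.
#' * `fit_classifier(x, labels, seed)` — train a binary classifier
#'   (`labels` logical, `TRUE` = positive); returns an opaque model.
#' * `predict_prob(model, x)` — positive-class probability in `[0, 1]`,
#'   one per row.
#'
#' @param fit_regressor,predict_regressor,fit_classifier,predict_prob the
#'   contract functions described above.
#' @param label short human-readable description.
#' @return an object of class `learner_spec`.
#' @seealso [learner_ranger()], [learner_mean()]
#' @export
learner_spec <- function(fit_regressor, predict_regressor, fit_classifier,
                         predict_prob, label = "custom") {
  for (f in list(fit_regressor, predict_regressor, fit_classifier,
                 predict_prob)) {
    if (!is.function(f)) abort("learner components must be functions",
                               "ensembin_input_error")
  }
  structure(list(fit_regressor = fit_regressor,
                 predict_regressor = predict_regressor,
                 fit_classifier = fit_classifier,
                 predict_prob = predict_prob,
                 label = label),
            class = "learner_spec")
}

#' @export
print.learner_spec <- function(x, ...) {
  cat(sprintf("<learner_spec> %s\n", x$label))
  invisible(x)
}

#' Random-forest base learner
#'
#' The default learner: \pkg{ranger} random forests for both roles, 1000
#' trees and package defaults otherwise. Classifiers are probability forests;
#' the positive-class probability is the fraction of trees voting positive.
#' `num_threads = 1` keeps fits fully deterministic under a seed.
#'
#' @param num_trees number of trees (default 1000).
#' @param mtry,min_node_size optional \pkg{ranger} hyperparameters; `NULL`
#'   leaves the \pkg{ranger} defaults in place.
#' @param num_threads threads per fit (default 1, deterministic).
#' @return a [learner_spec()].
#' @export
learner_ranger <- function(num_trees = 1000L, mtry = NULL,
                           min_node_size = NULL, num_threads = 1L) {
  common <- list(num.trees = num_trees, num.threads = num_threads,
                 verbose = FALSE)
  if (!is.null(mtry)) common$mtry <- mtry
  if (!is.null(min_node_size)) common$min.node.size <- min_node_size
  learner_spec(
    fit_regressor = function(x, y, seed = NULL) {
      args <- c(list(x = as.data.frame(x), y = y, seed = seed), common)
      do.call(ranger::ranger, args)
    },
    predict_regressor = function(model, x) {
      stats::predict(model, data = as.data.frame(x),
                     num.threads = num_threads)$predictions
    },
    fit_classifier = function(x, labels, seed = NULL) {
      yf <- factor(ifelse(labels, "pos", "neg"), levels = c("neg", "pos"))
      args <- c(list(x = as.data.frame(x), y = yf, seed = seed,
                     probability = TRUE), common)
      do.call(ranger::ranger, args)
    },
    predict_prob = function(model, x) {
      pr <- stats::predict(model, data = as.data.frame(x),
                           num.threads = num_threads)$predictions
      as.numeric(pr[, "pos"])
    },
    label = sprintf("ranger random forest (%d trees)", num_trees))
}

#' Trivial mean/constant base learner
#'
#' A deliberately information-free learner: the regressor predicts the mean
#' of its training response and the classifier a constant probability. Useful
#' for verifying the ensemble wiring analytically — with this learner the
#' final prediction is exactly the mean of the per-bin response means.
#'
#' @param prob the constant positive-class probability (default 0.5).
#' @return a [learner_spec()].
#' @export
learner_mean <- function(prob = 0.5) {
  learner_spec(
    fit_regressor = function(x, y, seed = NULL) mean(y),
    predict_regressor = function(model, x) rep(model, nrow(as_feature_matrix(x))),
    fit_classifier = function(x, labels, seed = NULL) prob,
    predict_prob = function(model, x) rep(model, nrow(as_feature_matrix(x))),
    label = "trivial mean regressor / constant-probability classifier")
}
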