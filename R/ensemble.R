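#' Fit a binned ensemble regressor
#'
#' Trains the core estimator: the continuous response is discretized into `c`
#' bins, each bin gets a regressor trained on *its own* samples only, and —
#' in weighted mode — a one-vs-rest classifier trained on the full training
#' set with that bin's samples as the positive class (optionally rebalanced
#' per `resampling`). A new sample is predicted by every bin's regressor; the
#' classifiers' positive-class probabilities, normalized to sum to one, weight
#' those predictions into the final value. With `aggregator = "averaging"` no
#' classifiers are trained and the per-bin predictions are simply averaged.
#'
#' Resampling touches only the classifier training sets; regressors always see
#' the raw bin samples. All randomness (discretization, resampling, base
#' learners) derives deterministically from `seed`, with independent per-bin
#' sub-streams.
#'
#' @param x numeric feature matrix (or data frame), one row per sample.
#' @param y numeric response vector, one value per row of `x`.
#' @param c number of bins (>= 1). `c = 1` degenerates to a single regressor
#'   trained on the full set, with weight 1.
#' @param discretizer one of `"even_split"`, `"equal_frequency"`, `"kmeans"`,
#'   `"random"`; see [discretize()].
#' @param aggregator `"weighted"` (classifier-probability weighting) or
#'   `"averaging"` (plain mean, no classifiers).
#' @param resampling a [resampling_spec()] for the classifier training sets.
#' @param learner a [learner_spec()]; default [learner_ranger()].
#' @param seed master integer seed.
#' @param kmeans_restarts restarts for the k-means discretizer.
#' @param min_bin_size smallest admissible bin (default 2): a regressor cannot
#'   be meaningfully trained on fewer samples.
#' @return an object of class `ensembin`: the fitted pairs, the
#'   [new_bin_assignment()], class-count bookkeeping for each classifier, and
#'   the specs needed to predict.
#' @examples
#' sim <- generate_synthetic(synthetic_spec(n_train = 120, n_test = 40, p = 5,
#'                                          n_targets = 1, seed = 1))
#' fit <- ensembin(sim$train$x, sim$train$y[, 1], c = 3,
#'                 learner = learner_ranger(num_trees = 50), seed = 1)
#' head(predict(fit, sim$test$x))
#' @export
ensembin <- function(x, y, c,
                     discretizer = c("even_split", "equal_frequency",
                                     "kmeans", "random"),
                     aggregator = c("weighted", "averaging"),
                     resampling = resampling_spec("none"),
                     learner = learner_ranger(),
                     seed = 1L, kmeans_restarts = 10L, min_bin_size = 2L) {
  discretizer <- match.arg(discretizer)
  aggregator <- match.arg(aggregator)
  stopifnot(inherits(resampling, "resampling_spec"),
            inherits(learner, "learner_spec"))
  x <- as_feature_matrix(x)
  check_response(y)
  if (length(y) != nrow(x)) {
    abort("response length must match the number of feature rows",
          "ensembin_input_error")
  }
  n <- nrow(x)
  c <- check_bin_count(c, n)
  if (n < 2L * c) {
    abort(sprintf("need at least 2*c = %d samples to fit %d bins (have %d)",
                  2L * c, c, n), "ensembin_input_error")
  }

  bins <- discretize(y, c, method = discretizer,
                     seed = spawn_seed(seed, "disc"),
                     restarts = kmeans_restarts)
  too_small <- which(bins$sizes < min_bin_size)
  if (length(too_small) > 0L) {
    abort(sprintf(
      "discretizer '%s' left bin %d with %d sample(s); a bin needs at least %d to train a regressor",
      discretizer, too_small[1L], bins$sizes[too_small[1L]], min_bin_size),
      "ensembin_empty_bin")
  }
  log_msg("info", "fit: method=%s c=%d aggregator=%s resampling=%s; bin sizes: %s",
          discretizer, c, aggregator, resampling$mode,
          paste(bins$sizes, collapse = ","))

  use_classifiers <- aggregator == "weighted" && c > 1L
  regressors <- vector("list", c)
  classifiers <- if (use_classifiers) vector("list", c) else NULL
  counts <- data.frame(bin = seq_len(c), n_bin = bins$sizes,
                       n_pos_raw = NA_integer_, n_neg_raw = NA_integer_,
                       n_pos_fit = NA_integer_, n_neg_fit = NA_integer_)

  for (b in seq_len(c)) {
    in_bin <- bins$labels == b
    regressors[[b]] <- learner$fit_regressor(
      x[in_bin, , drop = FALSE], y[in_bin], seed = spawn_seed(seed, "reg", b))
    if (use_classifiers) {
      rs <- apply_resampling(x, in_bin, resampling,
                             seed = spawn_seed(seed, "res", b))
      counts$n_pos_raw[b] <- sum(in_bin)
      counts$n_neg_raw[b] <- sum(!in_bin)
      counts$n_pos_fit[b] <- sum(rs$labels)
      counts$n_neg_fit[b] <- sum(!rs$labels)
      log_msg("debug", "  bin %d classifier set: %d+/%d- (raw %d+/%d-)",
              b, counts$n_pos_fit[b], counts$n_neg_fit[b],
              counts$n_pos_raw[b], counts$n_neg_raw[b])
      classifiers[[b]] <- learner$fit_classifier(
        rs$features, rs$labels, seed = spawn_seed(seed, "clf", b))
    }
  }

  structure(list(bins = bins, regressors = regressors,
                 classifiers = classifiers, aggregator = aggregator,
                 resampling = resampling, learner = learner, seed = seed,
                 n_train = n, n_features = ncol(x),
                 feature_names = colnames(x), class_counts = counts),
            class = "ensembin")
}

#' @export
print.ensembin <- function(x, ...) {
  cat(sprintf("<ensembin> %d bins (%s), aggregator = %s, resampling = %s\n",
              x$bins$c, x$bins$method, x$aggregator, x$resampling$mode))
  cat(sprintf("  learner: %s; trained on %d samples x %d features\n",
              x$learner$label, x$n_train, x$n_features))
  cat("  bin sizes:", paste(x$bins$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Normalize classifier probabilities into aggregation weights
#'
#' Divides each probability by the probability sum, yielding non-negative
#' weights that sum to one. An all-zero probability vector (the normalization
#' would divide by zero) falls back to uniform weights, so the final
#' prediction degrades gracefully to plain averaging.
#'
#' @param probabilities numeric vector of values in `[0, 1]`.
#' @return numeric weight vector of the same length, summing to 1.
#' @examples
#' normalize_weights(c(0.4, 0.4, 0.2))  # 0.4 0.4 0.2
#' normalize_weights(c(0, 0, 0))        # uniform fallback
#' @export
normalize_weights <- function(probabilities) {
  p <- probabilities
  if (!is.numeric(p) || length(p) < 1L || anyNA(p) ||
      any(p < -1e-9) || any(p > 1 + 1e-9)) {
    abort("probabilities must be numeric values in [0, 1]",
          "ensembin_contract_error")
  }
  p <- pmin(pmax(p, 0), 1)
  s <- sum(p)
  if (s <= 0) rep(1 / length(p), length(p)) else p / s
}

# row-wise weight normalization with the uniform fallback
normalize_weight_rows <- function(probs) {
  if (any(probs < -1e-9) || any(probs > 1 + 1e-9)) {
    abort("classifier returned a probability outside [0, 1]",
          "ensembin_contract_error")
  }
  probs <- pmin(pmax(probs, 0), 1)
  s <- rowSums(probs)
  zero <- s <= 0
  s[zero] <- 1
  w <- probs / s
  w[zero, ] <- 1 / ncol(probs)
  w
}

check_newdata <- function(object, newdata) {
  x <- as_feature_matrix(newdata)
  if (ncol(x) != object$n_features) {
    abort(sprintf("newdata has %d features but the model was trained on %d",
                  ncol(x), object$n_features), "ensembin_input_error")
  }
  if (!is.null(object$feature_names) && !is.null(colnames(x)) &&
      !identical(colnames(x), object$feature_names)) {
    x <- x[, object$feature_names, drop = FALSE]
  }
  x
}

#' Predict from a binned ensemble
#'
#' Runs every bin's regressor and (in weighted mode) classifier on the new
#' samples, normalizes the probabilities into weights, and returns the
#' weighted combination. Every final value is a convex combination of the
#' per-bin regressor outputs.
#'
#' @param object a fitted [ensembin()] model.
#' @param newdata feature matrix with the training feature arity.
#' @param type `"response"` for the numeric predictions, `"breakdown"` for a
#'   `prediction_breakdown` carrying per-bin predictions, probabilities,
#'   weights and finals.
#' @param ... unused.
#' @return numeric vector, or a `prediction_breakdown` (list with matrices
#'   `predictions`, `probabilities`, `weights` and vector `final`).
#' @export
predict.ensembin <- function(object, newdata,
                             type = c("response", "breakdown"), ...) {
  type <- match.arg(type)
  x <- check_newdata(object, newdata)
  n <- nrow(x)
  c <- object$bins$c
  if (n == 0L) {
    out <- list(predictions = matrix(numeric(0), 0L, c),
                probabilities = matrix(numeric(0), 0L, c),
                weights = matrix(numeric(0), 0L, c), final = numeric(0))
    class(out) <- "prediction_breakdown"
    return(if (type == "response") out$final else out)
  }
  preds <- vapply(seq_len(c), function(b) {
    as.numeric(object$learner$predict_regressor(object$regressors[[b]], x))
  }, numeric(n))
  preds <- matrix(preds, nrow = n)
  if (object$aggregator == "averaging" || c == 1L) {
    probs <- matrix(NA_real_, n, c)
    weights <- matrix(1 / c, n, c)
  } else {
    probs <- vapply(seq_len(c), function(b) {
      as.numeric(object$learner$predict_prob(object$classifiers[[b]], x))
    }, numeric(n))
    probs <- matrix(probs, nrow = n)
    weights <- normalize_weight_rows(probs)
  }
  final <- rowSums(preds * weights)
  if (type == "response") return(final)
  structure(list(predictions = preds, probabilities = probs,
                 weights = weights, final = final),
            class = "prediction_breakdown")
}

#' @export
print.prediction_breakdown <- function(x, ...) {
  cat(sprintf("<prediction_breakdown> %d sample(s), %d bins\n",
              length(x$final), ncol(x$predictions)))
  if (length(x$final) == 1L) {
    cat("  per-bin predictions:", paste(signif(x$predictions[1, ], 5),
                                        collapse = ", "), "\n")
    cat("  weights:", paste(signif(x$weights[1, ], 5), collapse = ", "), "\n")
    cat("  final:", signif(x$final, 6), "\n")
  } else {
    cat("  finals:", paste(signif(utils::head(x$final, 6), 5), collapse = ", "),
        if (length(x$final) > 6) "...", "\n")
  }
  invisible(x)
}

#' Predict a single sample with its full breakdown
#'
#' @param model a fitted [ensembin()] model.
#' @param x a single feature vector (or one-row matrix).
#' @return a `prediction_breakdown` for one sample.
#' @export
predict_one <- function(model, x) {
  x <- as_feature_matrix(if (is.null(dim(x))) matrix(x, nrow = 1L) else x)
  if (nrow(x) != 1L) {
    abort("predict_one expects exactly one sample", "ensembin_input_error")
  }
  predict.ensembin(model, x, type = "breakdown")
}

#' Fit the base-case single regressor
#'
#' The comparison baseline throughout: one regressor trained on the full,
#' undiscretized training set. It uses the same derived seed stream as the
#' first (and only) bin of a one-bin ensemble, so `ensembin(..., c = 1)` and
#' `fit_base(...)` with the same master seed produce identical predictions.
#'
#' @inheritParams ensembin
#' @return an object of class `ensembin_base`.
#' @export
fit_base <- function(x, y, learner = learner_ranger(), seed = 1L) {
  x <- as_feature_matrix(x)
  check_response(y)
  if (length(y) != nrow(x)) {
    abort("response length must match the number of feature rows",
          "ensembin_input_error")
  }
  model <- learner$fit_regressor(x, y, seed = spawn_seed(seed, "reg", 1L))
  structure(list(model = model, learner = learner, seed = seed,
                 n_features = ncol(x), feature_names = colnames(x)),
            class = "ensembin_base")
}

#' @export
predict.ensembin_base <- function(object, newdata, ...) {
  x <- as_feature_matrix(newdata)
  if (ncol(x) != object$n_features) {
    abort(sprintf("newdata has %d features but the model was trained on %d",
                  ncol(x), object$n_features), "ensembin_input_error")
  }
  if (!is.null(object$feature_names) && !is.null(colnames(x)) &&
      !identical(colnames(x), object$feature_names)) {
    x <- x[, object$feature_names, drop = FALSE]
  }
  as.numeric(object$learner$predict_regressor(object$model, x))
}

## persistence --------------------------------------------------------------

MODEL_FORMAT <- "ensembin_model"
MODEL_VERSION <- 1L

#' Save / load fitted models
#'
#' Models are wrapped in a self-describing versioned container before being
#' written, so a loaded file can be validated and future format changes can be
#' migrated explicitly. Works for single [ensembin()]/[fit_base()] models and
#' for named lists of per-target models.
#'
#' @param model the fitted model (or named list of models) to save.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = MODEL_FORMAT, version = MODEL_VERSION, model = model),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("model file not found: %s", path), "ensembin_io_error")
  }
  obj <- tryCatch(readRDS(path), error = function(e) {
    abort(sprintf("cannot read model file %s: %s", path, conditionMessage(e)),
          "ensembin_io_error")
  })
  if (!is.list(obj) || !identical(obj$format, MODEL_FORMAT)) {
    abort(sprintf("%s is not an ensembin model file", path),
          "ensembin_io_error")
  }
  if (!identical(obj$version, MODEL_VERSION)) {
    abort(sprintf("unsupported model format version %s", obj$version),
          "ensembin_io_error")
  }
  obj$model
}
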