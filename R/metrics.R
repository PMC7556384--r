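#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` with the total sum of squares taken about the
#' observed mean. Unbounded below: a value below zero means the predictions
#' fit worse than the horizontal line at the observed mean.
#'
#' @param observed numeric vector of observed values (not constant).
#' @param predicted numeric vector of predictions, same length.
#' @return a single numeric value, at most 1.
#' @examples
#' r_squared(c(0, 1), c(1, 0))  # -3
#' @export
r_squared <- function(observed, predicted) {
  if (!is.numeric(observed) || !is.numeric(predicted) ||
      length(observed) != length(predicted) || length(observed) < 2L) {
    abort("observed and predicted must be numeric vectors of equal length >= 2",
          "ensembin_input_error")
  }
  if (anyNA(observed) || anyNA(predicted)) {
    abort("missing values in observed or predicted", "ensembin_input_error")
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    abort("observed vector is constant: R-squared denominator is zero",
          "ensembin_degenerate_metric")
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Binary classification metrics
#'
#' Accuracy, precision, recall and F1 from the confusion matrix of a binary
#' prediction. Zero-denominator conventions: precision is 0 when nothing is
#' predicted positive, recall is 0 when nothing is actually positive, and F1
#' is 0 when precision + recall is 0.
#'
#' @param actual binary vector of true labels (logical, 0/1, or 2-level
#'   factor; `TRUE`/1/last level = positive).
#' @param predicted binary vector of predicted labels, same length.
#' @return a list with `accuracy`, `precision`, `recall`, `f1` and the
#'   confusion counts `tp`, `fp`, `tn`, `fn`.
#' @examples
#' m <- classification_metrics(c(1, 1, 0, 0), c(1, 1, 1, 1))
#' c(m$precision, m$recall, round(m$f1, 2))  # 0.5 1 0.67
#' @export
classification_metrics <- function(actual, predicted) {
  a <- as_binary(actual)
  p <- as_binary(predicted)
  if (length(a) != length(p) || length(a) < 1L) {
    abort("actual and predicted must have equal length >= 1",
          "ensembin_input_error")
  }
  tp <- sum(a & p); fp <- sum(!a & p); tn <- sum(!a & !p); fn <- sum(a & !p)
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(accuracy = (tp + tn) / length(a), precision = precision,
       recall = recall, f1 = f1, tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Mean percentage performance difference against a baseline
#'
#' For each target, the percentage difference `100 * (method - base) / |base|`
#' is computed, and the mean over targets is returned. The absolute value in
#' the denominator keeps the sign meaningful when a base score is negative,
#' but note that near-zero baselines still produce very large magnitudes.
#' Targets with a base score of exactly 0 are excluded with a warning.
#'
#' @param base numeric vector of per-target baseline scores.
#' @param method numeric vector of per-target method scores, same length.
#' @return the mean percentage difference (positive = method better when the
#'   scores are higher-is-better).
#' @examples
#' percent_difference(c(0.1, 0.2), c(0.2, 0.4))  # 100
#' @export
percent_difference <- function(base, method) {
  if (!is.numeric(base) || !is.numeric(method) ||
      length(base) != length(method) || length(base) < 1L) {
    abort("base and method must be numeric vectors of equal length",
          "ensembin_input_error")
  }
  zero <- base == 0
  if (any(zero)) {
    warning(sprintf(
      "%d target(s) with base score exactly 0 excluded from the percentage difference",
      sum(zero)))
    base <- base[!zero]; method <- method[!zero]
    if (length(base) == 0L) return(NA_real_)
  }
  mean(100 * (method - base) / abs(base))
}

#' Paired t-test between per-target score vectors
#'
#' Two-sided paired t-test across targets, as used to compare a method's
#' per-target scores against the base case. No multiple-testing correction is
#' applied; when several comparisons are reported side by side, interpret the
#' p-values accordingly.
#'
#' @param base,method numeric per-target score vectors (>= 3 pairs).
#' @return a list with `statistic` (t), `p_value`, `df` and
#'   `mean_difference` (method minus base).
#' @export
paired_comparison <- function(base, method) {
  if (!is.numeric(base) || !is.numeric(method) ||
      length(base) != length(method) || length(base) < 3L) {
    abort("paired comparison needs numeric vectors of equal length >= 3",
          "ensembin_input_error")
  }
  d <- method - base
  if (stats::sd(d) < 1e-10 * (1 + abs(mean(d)))) {
    abort("differences have zero variance: paired t-test is degenerate",
          "ensembin_degenerate_test")
  }
  tt <- stats::t.test(method, base, paired = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_difference = mean(d))
}
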