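#' Resampling specification for classifier training sets
#'
#' Describes how each bin's one-vs-rest classification set is balanced before
#' the classifier is trained. Resampling is applied *only* to classifier
#' training sets, never to the per-bin regressors.
#'
#' @param mode `"none"` (train on the imbalanced set as-is), `"undersample"`
#'   (randomly drop majority rows down to the minority count), or
#'   `"oversample"` (grow the minority to the majority count with SMOTE).
#' @param k SMOTE neighbour count (default 5); ignored unless
#'   `mode = "oversample"`.
#' @param seed optional seed; when `NULL` the ensemble fit derives one from
#'   its master seed.
#' @return an object of class `resampling_spec`.
#' @export
resampling_spec <- function(mode = c("none", "undersample", "oversample"),
                            k = 5L, seed = NULL) {
  mode <- match.arg(mode)
  if (length(k) != 1L || is.na(k) || k != round(k) || k < 1L) {
    abort("SMOTE neighbour count k must be a single integer >= 1",
          "ensembin_input_error")
  }
  structure(list(mode = mode, k = as.integer(k), seed = seed),
            class = "resampling_spec")
}

# coerce a binary label vector (logical, 0/1 numeric, or 2-level factor) to
# logical, TRUE = positive
as_binary <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) {
    if (nlevels(labels) > 2L) {
      abort("labels must be binary", "ensembin_input_error")
    }
    return(labels == levels(labels)[nlevels(labels)])
  }
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(labels == 1)
  abort("labels must be logical, 0/1 numeric, or a 2-level factor",
        "ensembin_input_error")
}

#' Random undersampling of the majority class
#'
#' Randomly drops majority-class rows (without replacement, under `seed`)
#' until both classes have the original minority count. Every returned row is
#' an original row; original row order is preserved. A balanced input is
#' returned unchanged.
#'
#' @param features numeric matrix (or data frame) of predictors, one row per
#'   sample.
#' @param labels binary vector (logical, 0/1, or 2-level factor), one per row.
#' @param seed integer seed for the majority draw.
#' @return a list with elements `features` (matrix) and `labels` (logical).
#' @export
undersample <- function(features, labels, seed = NULL) {
  x <- as_feature_matrix(features)
  lab <- as_binary(labels)
  if (length(lab) != nrow(x)) {
    abort("labels length must match the number of feature rows",
          "ensembin_input_error")
  }
  n_pos <- sum(lab); n_neg <- sum(!lab)
  if (n_pos == 0L || n_neg == 0L) {
    abort("undersampling needs both classes present", "ensembin_degenerate_class")
  }
  if (n_pos == n_neg) return(list(features = x, labels = lab))
  maj <- lab == (n_pos > n_neg)
  keep_maj <- with_seed(seed, sample(which(maj), min(n_pos, n_neg)))
  idx <- sort(c(which(!maj), keep_maj))
  list(features = x[idx, , drop = FALSE], labels = lab[idx])
}

#' SMOTE oversampling of the minority class
#'
#' Grows the minority class to the majority count by synthetic minority
#' oversampling: each synthetic row is `x + u * (x' - x)` for a minority row
#' `x`, one of its `k` nearest minority neighbours `x'` (Euclidean distance on
#' the raw features), and `u` drawn uniformly from `[0, 1]`. All original rows
#' are retained, synthetic rows are appended. If the minority has `m <= k`
#' members the neighbour count is clamped to `m - 1`; a singleton minority is
#' balanced by duplication. A balanced input is returned unchanged.
#'
#' Distances are computed on the raw feature scale; pre-standardize if your
#' features have heterogeneous scales.
#'
#' @inheritParams undersample
#' @param k number of nearest minority neighbours to interpolate towards.
#' @return a list with elements `features` and `labels`; originals first, then
#'   the synthetic minority rows.
#' @export
smote_oversample <- function(features, labels, k = 5L, seed = NULL) {
  x <- as_feature_matrix(features)
  lab <- as_binary(labels)
  if (length(lab) != nrow(x)) {
    abort("labels length must match the number of feature rows",
          "ensembin_input_error")
  }
  if (length(k) != 1L || is.na(k) || k < 1L) {
    abort("k must be a single integer >= 1", "ensembin_input_error")
  }
  n_pos <- sum(lab); n_neg <- sum(!lab)
  if (n_pos == 0L || n_neg == 0L) {
    abort("SMOTE needs at least one member in each class",
          "ensembin_degenerate_class")
  }
  if (n_pos == n_neg) return(list(features = x, labels = lab))
  minority <- lab == (n_pos < n_neg)
  m <- sum(minority)
  need <- abs(n_pos - n_neg)
  xmin <- x[minority, , drop = FALSE]
  synth <- with_seed(seed, {
    if (m == 1L) {
      # duplication fallback: no neighbour to interpolate towards
      xmin[rep(1L, need), , drop = FALSE]
    } else {
      kk <- min(as.integer(k), m - 1L)
      d <- as.matrix(stats::dist(xmin))
      nn <- t(apply(d, 1L, function(row) order(row)[2:(kk + 1L)]))
      nn <- matrix(nn, nrow = m)            # kk = 1 edge: keep matrix shape
      base <- sample.int(m, need, replace = TRUE)
      pick <- if (kk == 1L) rep(1L, need) else sample.int(kk, need, replace = TRUE)
      u <- stats::runif(need)
      nb <- nn[cbind(base, pick)]
      xmin[base, , drop = FALSE] +
        u * (xmin[nb, , drop = FALSE] - xmin[base, , drop = FALSE])
    }
  })
  rownames(synth) <- NULL
  out_x <- rbind(x, synth)
  rownames(out_x) <- NULL
  list(features = out_x,
       labels = c(lab, rep(n_pos < n_neg, need)))
}

#' Apply a resampling specification
#'
#' @param features,labels as in [undersample()].
#' @param spec a [resampling_spec()].
#' @param seed seed overriding `spec$seed`.
#' @return a list with `features` and `labels`; `mode = "none"` returns the
#'   input untouched.
#' @export
apply_resampling <- function(features, labels, spec, seed = NULL) {
  stopifnot(inherits(spec, "resampling_spec"))
  seed <- seed %||% spec$seed
  switch(spec$mode,
         none        = list(features = as_feature_matrix(features),
                            labels = as_binary(labels)),
         undersample = undersample(features, labels, seed = seed),
         oversample  = smote_oversample(features, labels, k = spec$k,
                                        seed = seed))
}
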