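# The aggregator names exposed to users bundle the weighting mode with the
# classifier-set resampling, mirroring how the four aggregation strategies
# are usually discussed: averaging (no classifiers), imbalanced (weighted,
# classifier sets left as-is), undersample, oversample (SMOTE).
aggregator_modes <- function(name, smote_k = 5L) {
  switch(name,
         averaging   = list(aggregator = "averaging",
                            resampling = resampling_spec("none")),
         imbalanced  = list(aggregator = "weighted",
                            resampling = resampling_spec("none")),
         undersample = list(aggregator = "weighted",
                            resampling = resampling_spec("undersample")),
         oversample  = list(aggregator = "weighted",
                            resampling = resampling_spec("oversample",
                                                         k = smote_k)),
         abort(sprintf("unknown aggregator '%s'", name),
               "ensembin_input_error"))
}

GRID_DISCRETIZERS <- c("random", "even_split", "equal_frequency", "kmeans")
GRID_AGGREGATORS <- c("averaging", "imbalanced", "undersample", "oversample")

#' Run the discretizer x aggregator x bin-size evaluation grid
#'
#' For every target column, fits the base-case single regressor plus one
#' ensemble per `(discretizer, aggregator, c)` cell, scores test-set
#' R-squared, and evaluates each cell's per-bin one-vs-rest classifiers
#' (accuracy, precision, recall, F1) against test bin membership derived from
#' the fitted discretization. Cells whose fit fails (for example an empty
#' equal-frequency bin) are recorded in the `errors` table and the grid
#' continues.
#'
#' Per-target randomness is derived from a hash of the target *name*, so the
#' report is invariant to target column order, and a `c = 1` cell reproduces
#' the base case exactly.
#'
#' Classifier test labels come from [assign_bins()]; a sample is predicted
#' positive for a bin when that bin's classifier probability is at least 0.5.
#'
#' @param train,test [as_dataset()] objects with identical feature arity and
#'   target columns.
#' @param c_list integer vector of bin counts (default `2:5`).
#' @param discretizers subset of
#'   `c("random", "even_split", "equal_frequency", "kmeans")`; an empty
#'   vector gives a base-case-only report.
#' @param aggregators subset of
#'   `c("averaging", "imbalanced", "undersample", "oversample")`.
#' @param learner a [learner_spec()].
#' @param smote_k SMOTE neighbour count for the oversample aggregator.
#' @param seed master seed for the whole grid.
#' @param kmeans_restarts restarts for the k-means discretizer.
#' @return an object of class `eval_report`: data frames `base` (per-target
#'   base R-squared), `regression` (per cell per target: R-squared and
#'   percentage difference vs base), `classifiers` (per bin: training class
#'   counts before/after resampling and the four metrics), `errors`, and a
#'   `meta` list.
#' @export
run_grid <- function(train, test, c_list = 2:5,
                     discretizers = GRID_DISCRETIZERS,
                     aggregators = GRID_AGGREGATORS,
                     learner = learner_ranger(), smote_k = 5L, seed = 1L,
                     kmeans_restarts = 10L) {
  stopifnot(inherits(train, "ensembin_dataset"),
            inherits(test, "ensembin_dataset"))
  if (ncol(train$x) != ncol(test$x)) {
    abort("train and test have different feature arity", "ensembin_input_error")
  }
  if (!all(colnames(train$y) %in% colnames(test$y))) {
    abort("test set is missing target columns present in train",
          "ensembin_input_error")
  }
  if (length(discretizers) > 0L) {
    discretizers <- match.arg(discretizers, GRID_DISCRETIZERS,
                              several.ok = TRUE)
  }
  if (length(aggregators) > 0L) {
    aggregators <- match.arg(aggregators, GRID_AGGREGATORS, several.ok = TRUE)
  }
  targets <- colnames(train$y)

  base_rows <- list(); reg_rows <- list(); clf_rows <- list(); err_rows <- list()
  for (target in targets) {
    y_tr <- train$y[, target]
    y_te <- test$y[, target]
    t_seed <- spawn_seed(seed, "cell", string_hash(target))
    base <- fit_base(train$x, y_tr, learner = learner, seed = t_seed)
    r2_base <- r_squared(y_te, predict(base, test$x))
    base_rows[[target]] <- data.frame(target = target, r2 = r2_base)
    log_msg("info", "grid: target %s base R2 = %.4f", target, r2_base)

    for (disc in discretizers) for (agg in aggregators) for (cc in c_list) {
      modes <- aggregator_modes(agg, smote_k = smote_k)
      fit <- tryCatch(
        ensembin(train$x, y_tr, c = cc, discretizer = disc,
                 aggregator = modes$aggregator, resampling = modes$resampling,
                 learner = learner, seed = t_seed,
                 kmeans_restarts = kmeans_restarts),
        error = function(e) e)
      if (inherits(fit, "error")) {
        err_rows[[length(err_rows) + 1L]] <- data.frame(
          target = target, discretizer = disc, aggregator = agg, c = cc,
          message = conditionMessage(fit))
        log_msg("warn", "grid cell failed (%s/%s/c=%d, %s): %s",
                disc, agg, cc, target, conditionMessage(fit))
        next
      }
      bd <- predict(fit, test$x, type = "breakdown")
      r2 <- r_squared(y_te, bd$final)
      pct <- if (r2_base == 0) NA_real_ else 100 * (r2 - r2_base) / abs(r2_base)
      reg_rows[[length(reg_rows) + 1L]] <- data.frame(
        target = target, discretizer = disc, aggregator = agg, c = cc,
        r2 = r2, r2_base = r2_base, pct_vs_base = pct)
      if (!is.null(fit$classifiers)) {
        test_bins <- assign_bins(fit$bins, y_te,
                                 seed = spawn_seed(t_seed, "test"))
        for (b in seq_len(cc)) {
          m <- classification_metrics(test_bins == b,
                                      bd$probabilities[, b] >= 0.5)
          cnt <- fit$class_counts[b, ]
          clf_rows[[length(clf_rows) + 1L]] <- data.frame(
            target = target, discretizer = disc, aggregator = agg, c = cc,
            bin = b, n_pos_raw = cnt$n_pos_raw, n_neg_raw = cnt$n_neg_raw,
            n_pos_fit = cnt$n_pos_fit, n_neg_fit = cnt$n_neg_fit,
            accuracy = m$accuracy, precision = m$precision,
            recall = m$recall, f1 = m$f1)
        }
      }
    }
  }
  bind <- function(rows, proto) {
    if (length(rows) == 0L) proto else do.call(rbind, c(rows,
                                                        make.row.names = FALSE))
  }
  structure(list(
    base = bind(base_rows, data.frame(target = character(0), r2 = numeric(0))),
    regression = bind(reg_rows, data.frame(
      target = character(0), discretizer = character(0),
      aggregator = character(0), c = integer(0), r2 = numeric(0),
      r2_base = numeric(0), pct_vs_base = numeric(0))),
    classifiers = bind(clf_rows, data.frame(
      target = character(0), discretizer = character(0),
      aggregator = character(0), c = integer(0), bin = integer(0),
      n_pos_raw = integer(0), n_neg_raw = integer(0), n_pos_fit = integer(0),
      n_neg_fit = integer(0), accuracy = numeric(0), precision = numeric(0),
      recall = numeric(0), f1 = numeric(0))),
    errors = bind(err_rows, data.frame(
      target = character(0), discretizer = character(0),
      aggregator = character(0), c = integer(0), message = character(0))),
    meta = list(seed = seed, c_list = c_list, discretizers = discretizers,
                aggregators = aggregators, smote_k = smote_k,
                learner = learner$label, targets = targets)),
    class = "eval_report")
}

#' Summarize an evaluation report across targets
#'
#' Mean test R-squared per `(discretizer, aggregator, c)` cell across
#' targets, plus the mean percentage difference against the base case
#' (computed per target, then averaged, with `|base|` in the denominator).
#'
#' @param object an `eval_report`.
#' @param ... unused.
#' @return a data frame, one row per grid cell.
#' @export
summary.eval_report <- function(object, ...) {
  reg <- object$regression
  if (nrow(reg) == 0L) {
    return(data.frame(discretizer = character(0), aggregator = character(0),
                      c = integer(0), mean_r2 = numeric(0),
                      mean_pct_vs_base = numeric(0), n_targets = integer(0)))
  }
  key <- interaction(reg$discretizer, reg$aggregator, reg$c, drop = TRUE)
  out <- do.call(rbind, lapply(split(reg, key), function(d) {
    data.frame(discretizer = d$discretizer[1L], aggregator = d$aggregator[1L],
               c = d$c[1L], mean_r2 = mean(d$r2),
               mean_pct_vs_base = mean(d$pct_vs_base), n_targets = nrow(d))
  }))
  out <- out[order(out$discretizer, out$aggregator, out$c), ]
  rownames(out) <- NULL
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d target(s), base mean R2 = %.4f\n",
              nrow(x$base), mean(x$base$r2)))
  if (nrow(x$regression) > 0L) {
    s <- summary(x)
    cat(sprintf("  %d grid cell(s); best: %s/%s c=%d (mean R2 %.4f)\n",
                nrow(s), s$discretizer[which.max(s$mean_r2)],
                s$aggregator[which.max(s$mean_r2)], s$c[which.max(s$mean_r2)],
                max(s$mean_r2)))
  }
  if (nrow(x$errors) > 0L) {
    cat(sprintf("  %d cell(s) failed; see $errors\n", nrow(x$errors)))
  }
  invisible(x)
}

#' Write an evaluation report to a directory
#'
#' Writes tidy CSVs (`base.csv`, `regression.csv`, `classifiers.csv`, and
#' `errors.csv` when any cell failed) plus a human-readable `summary.txt`
#' stating the metric conventions. Output is deterministic: the same report
#' always produces byte-identical files.
#'
#' @param report an `eval_report`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "eval_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE, quote = FALSE)
  }
  wr(report$base, "base.csv")
  wr(report$regression, "regression.csv")
  wr(report$classifiers, "classifiers.csv")
  if (nrow(report$errors) > 0L) wr(report$errors, "errors.csv")
  s <- summary(report)
  con <- file(file.path(dir, "summary.txt"), "w")
  on.exit(close(con))
  writeLines(c(
    "Binned ensemble regression evaluation report",
    sprintf("seed: %d | bins: %s | learner: %s",
            report$meta$seed, paste(report$meta$c_list, collapse = ","),
            report$meta$learner),
    sprintf("targets: %s", paste(report$meta$targets, collapse = ", ")),
    "",
    "Conventions: precision := 0 when nothing is predicted positive;",
    "F1 := 0 when precision + recall = 0; percentage difference uses",
    "100 * (method - base) / |base| (unstable for near-zero base scores);",
    "classifier metrics are averaged across bins with equal weight;",
    "paired comparisons are reported without multiple-testing correction.",
    "",
    sprintf("Base-case mean R2 across targets: %.6f", mean(report$base$r2)),
    "",
    "Mean R2 per grid cell (across targets):",
    utils::capture.output(print(format(s, digits = 4), row.names = FALSE))),
    con)
  invisible(dir)
}
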