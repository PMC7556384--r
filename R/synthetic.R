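#' Specification for the regime-structured synthetic generator
#'
#' Describes a multi-target regression problem shaped like a drug-perturbation
#' gene-expression panel: a few hundred training and test samples, many
#' continuous perturbation-condition features of which few are informative,
#' and a handful of continuous response columns. The response has *regime*
#' structure — latent, largely disjoint response bands with distinct
#' feature-to-response maps — so bin membership is predictable from the
#' features and per-bin specialization is rewarded.
#'
#' One designated carrier feature encodes the regime: its mean is shifted by
#' `feature_shift` per regime step (within-regime standard deviation 0.4),
#' and the response rises linearly along it with slope
#' `regime_gap / feature_shift`, so consecutive regime response bands are
#' centered `regime_gap` apart. Each regime additionally has its own dense
#' linear map over the remaining features (coefficient norm 0.6), plus
#' Gaussian noise. The many uninformative features emulate the broad
#' perturbation-condition encodings of expression panels.
#'
#' Default sample counts are a 10x scale-down of the motivating study shape
#' (7000/3000 samples): 700 training and 300 test samples.
#'
#' @param n_train,n_test sample counts (defaults 700 / 300).
#' @param p feature count (default 150; one carrier + p - 1 mostly
#'   uninformative features).
#' @param n_targets number of response columns (default 2).
#' @param n_regimes latent response bands with distinct linear maps
#'   (default 4).
#' @param noise_sd within-regime Gaussian noise standard deviation, in
#'   response units (default 0.8).
#' @param outlier_fraction fraction of samples receiving inflated-variance
#'   responses (heavy-tail contamination, standard deviation
#'   `1.5 * regime_gap`); default 0.02.
#' @param regime_gap spacing between consecutive regime response-band
#'   centers (default 9); with the fixed within-band spread this keeps
#'   adjacent bands largely disjoint.
#' @param feature_shift per-regime mean shift of the carrier feature
#'   (default 3); large relative to the carrier's within-regime spread, so
#'   regimes — and hence bins — are identifiable from the features.
#' @param seed master seed; generation is fully deterministic given the spec.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_train = 700L, n_test = 300L, p = 150L,
                           n_targets = 2L, n_regimes = 4L, noise_sd = 0.8,
                           outlier_fraction = 0.02, regime_gap = 9,
                           feature_shift = 3, seed = 1L) {
  spec <- list(n_train = as.integer(n_train), n_test = as.integer(n_test),
               p = as.integer(p), n_targets = as.integer(n_targets),
               n_regimes = as.integer(n_regimes), noise_sd = noise_sd,
               outlier_fraction = outlier_fraction, regime_gap = regime_gap,
               feature_shift = feature_shift, seed = as.integer(seed))
  bad <- character(0)
  for (f in c("n_train", "n_test", "p", "n_targets", "n_regimes")) {
    if (is.na(spec[[f]]) || spec[[f]] < 1L) bad <- c(bad, f)
  }
  if (spec$p < 2L) bad <- c(bad, "p")
  if (is.na(noise_sd) || noise_sd < 0) bad <- c(bad, "noise_sd")
  if (is.na(outlier_fraction) || outlier_fraction < 0 || outlier_fraction >= 1) {
    bad <- c(bad, "outlier_fraction")
  }
  if (is.na(regime_gap) || regime_gap < 0) bad <- c(bad, "regime_gap")
  if (is.na(feature_shift) || feature_shift <= 0) bad <- c(bad, "feature_shift")
  bad <- unique(bad)
  if (length(bad) > 0L) {
    abort(paste0("invalid synthetic spec field(s): ",
                 paste(bad, collapse = ", ")), "ensembin_input_error")
  }
  structure(spec, class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_spec> %d train / %d test, p = %d, %d target(s), %d regime(s)\n",
    x$n_train, x$n_test, x$p, x$n_targets, x$n_regimes))
  cat(sprintf("  noise_sd = %g, outlier_fraction = %g, regime_gap = %g, seed = %d\n",
              x$noise_sd, x$outlier_fraction, x$regime_gap, x$seed))
  invisible(x)
}

# fixed generator constants (response units are arbitrary expression units):
# carrier within-regime spread, and the norm of each regime's dense map
CARRIER_SD <- 0.4
DENSE_NORM <- 0.6

#' Generate a regime-structured synthetic regression problem
#'
#' Each sample is drawn by (i) sampling a latent regime uniformly, (ii)
#' drawing features — standard normal except the carrier feature, whose mean
#' is shifted by the regime — and (iii) computing each response as a linear
#' function of the carrier plus the regime's own dense linear map of the
#' remaining features plus Gaussian noise. Regimes are ordered along the
#' carrier, so the response bands are ordered and largely disjoint. An
#' `outlier_fraction` of samples additionally receives heavy-tailed response
#' noise, emulating the contamination that makes k-means discretization
#' isolate tiny outlier bins.
#'
#' @param spec a [synthetic_spec()].
#' @return a list of class `ensembin_sim` with elements `train` and `test`
#'   ([as_dataset()] objects), `regimes` and `outliers` (per-set labels), and
#'   `truth` (slope, regime offsets, dense coefficient array) for oracle
#'   checks.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  R <- spec$n_regimes; p <- spec$p; Tn <- spec$n_targets
  slope <- spec$regime_gap / spec$feature_shift
  with_seed(spec$seed, {
    # per-regime, per-target dense maps over the non-carrier features
    dense <- array(stats::rnorm(R * Tn * (p - 1L)), dim = c(R, Tn, p - 1L))
    for (r in seq_len(R)) for (t in seq_len(Tn)) {
      z <- dense[r, t, ]
      dense[r, t, ] <- DENSE_NORM * z / sqrt(sum(z^2))
    }
    draw <- function(n) {
      regime <- sample.int(R, n, replace = TRUE)
      x <- matrix(stats::rnorm(n * p), n, p)
      x[, 1L] <- (regime - (R + 1) / 2) * spec$feature_shift +
        stats::rnorm(n, 0, CARRIER_SD)
      is_out <- stats::runif(n) < spec$outlier_fraction
      y <- matrix(0, n, Tn)
      for (t in seq_len(Tn)) {
        sig <- vapply(seq_len(n), function(i) {
          sum(x[i, -1L] * dense[regime[i], t, ])
        }, numeric(1))
        y[, t] <- slope * x[, 1L] + sig + stats::rnorm(n, 0, spec$noise_sd)
        if (any(is_out)) {
          y[is_out, t] <- y[is_out, t] +
            stats::rnorm(sum(is_out), 0, 1.5 * spec$regime_gap)
        }
      }
      colnames(x) <- paste0("f", seq_len(p))
      colnames(y) <- paste0("g", seq_len(Tn))
      list(ds = as_dataset(x, y), regime = regime, outlier = is_out)
    }
    tr <- draw(spec$n_train)
    te <- draw(spec$n_test)
  })
  structure(list(train = tr$ds, test = te$ds,
                 regimes = list(train = tr$regime, test = te$regime),
                 outliers = list(train = tr$outlier, test = te$outlier),
                 truth = list(slope = slope, dense = dense,
                              carrier_sd = CARRIER_SD,
                              feature_shift = spec$feature_shift),
                 spec = spec),
            class = "ensembin_sim")
}

#' Oracle predictions from the true generating map
#'
#' Evaluates the noiseless regime-specific linear map on a dataset, given the
#' true regime labels. Used to check identifiability: with zero noise and no
#' contamination the oracle attains an R-squared of exactly 1.
#'
#' @param sim an `ensembin_sim` from [generate_synthetic()].
#' @param which `"train"` or `"test"`.
#' @param target target index.
#' @return numeric vector of oracle predictions.
#' @export
oracle_predictions <- function(sim, which = c("test", "train"), target = 1L) {
  which <- match.arg(which)
  ds <- sim[[which]]
  regime <- sim$regimes[[which]]
  tr <- sim$truth
  vapply(seq_len(nrow(ds$x)), function(i) {
    tr$slope * ds$x[i, 1L] + sum(ds$x[i, -1L] * tr$dense[regime[i], target, ])
  }, numeric(1))
}

#' Write a simulated train/test pair to disk
#'
#' Writes `train.csv` and `test.csv` (plus, optionally, the true regime
#' labels) under `dir`. Files are plain delimited text that round-trips
#' through [read_dataset()]; generation is seed-deterministic, so the same
#' spec always produces byte-identical files.
#'
#' @param sim an `ensembin_sim`.
#' @param dir output directory (created if needed).
#' @param include_regimes also write `regimes_train.csv` / `regimes_test.csv`.
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(sim, dir, include_regimes = FALSE) {
  stopifnot(inherits(sim, "ensembin_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(train = file.path(dir, "train.csv"),
             test = file.path(dir, "test.csv"))
  write_dataset(sim$train, paths[["train"]])
  write_dataset(sim$test, paths[["test"]])
  if (include_regimes) {
    for (w in c("train", "test")) {
      rp <- file.path(dir, paste0("regimes_", w, ".csv"))
      utils::write.csv(data.frame(regime = sim$regimes[[w]]), rp,
                       row.names = FALSE, quote = FALSE)
      paths[[paste0("regimes_", w)]] <- rp
    }
  }
  invisible(paths)
}
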