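#' Bin assignments for a continuous response
#'
#' A `bin_assignment` records an exhaustive, disjoint mapping of samples to
#' bins `1..c` together with the discretizer that produced it and whatever
#' fitted state (cut points or cluster centers) is needed to place *new*
#' response values into the same bins.
#'
#' All four discretizers guarantee that every bin is non-empty after fitting.
#' The three value-driven methods (`even_split`, `equal_frequency`, `kmeans`)
#' are order-respecting: if `y[i] < y[j]` then `bin(i) <= bin(j)`.
#'
#' @param labels integer vector of per-sample bin indices in `1..c`.
#' @param c number of bins.
#' @param method one of `"random"`, `"even_split"`, `"equal_frequency"`,
#'   `"kmeans"`.
#' @param seed the seed used (if the method is stochastic), else `NULL`.
#' @param cuts numeric cut points (value-boundary methods), else `NULL`.
#' @param centers sorted cluster centers (`kmeans`), else `NULL`.
#' @return an object of class `bin_assignment` with fields `labels`, `c`,
#'   `method`, `seed`, `cuts`, `centers` and `sizes`.
#' @keywords internal
new_bin_assignment <- function(labels, c, method, seed = NULL, cuts = NULL,
                               centers = NULL) {
  labels <- as.integer(labels)
  sizes <- tabulate(labels, nbins = c)
  empty <- which(sizes == 0L)
  if (length(empty) > 0L) {
    abort(sprintf("discretizer '%s' produced an empty bin (bin %d of %d)",
                  method, empty[1L], c), "ensembin_empty_bin")
  }
  structure(list(labels = labels, c = as.integer(c), method = method,
                 seed = seed, cuts = cuts, centers = centers, sizes = sizes),
            class = "bin_assignment")
}

#' @export
print.bin_assignment <- function(x, ...) {
  cat(sprintf("<bin_assignment> method = %s, c = %d, n = %d\n",
              x$method, x$c, length(x$labels)))
  cat("  bin sizes:", paste(x$sizes, collapse = ", "), "\n")
  if (!is.null(x$cuts)) cat("  cut points:",
                            paste(signif(x$cuts, 5), collapse = ", "), "\n")
  if (!is.null(x$centers)) cat("  centers:",
                               paste(signif(x$centers, 5), collapse = ", "), "\n")
  invisible(x)
}

# equal-as-possible block sizes: the first n %% c bins get one extra sample
split_sizes <- function(n, c) {
  base <- n %/% c
  extra <- n %% c
  base + as.integer(seq_len(c) <= extra)
}

#' Random discretization
#'
#' Shuffles the samples under `seed` and splits them into `c`
#' equal-as-possible blocks, so every bin's response follows the overall
#' response distribution. This is the bagging-like control among the
#' discretizers: it deliberately ignores the response values.
#'
#' @param y numeric response vector.
#' @param c number of bins (`1 <= c <= length(y)`).
#' @param seed integer seed; fixed seed gives identical labels.
#' @return a [new_bin_assignment()] object.
#' @examples
#' discretize_random(rnorm(10), c = 2, seed = 1)
#' @export
discretize_random <- function(y, c, seed = NULL) {
  check_response(y)
  n <- length(y)
  c <- check_bin_count(c, n)
  perm <- with_seed(seed, sample.int(n))
  labels <- integer(n)
  labels[perm] <- rep.int(seq_len(c), split_sizes(n, c))
  new_bin_assignment(labels, c, "random", seed = seed)
}

#' Even-split discretization
#'
#' Sorts the samples by response (stable on ties: original order preserved)
#' and assigns consecutive blocks to bins `1..c`. Bin sizes differ by at most
#' one; the first `n %% c` bins receive the extra sample. Duplicated response
#' values may be split across a bin boundary, which is exactly what
#' distinguishes this method from equal-frequency binning.
#'
#' @inheritParams discretize_random
#' @return a [new_bin_assignment()] object; `cuts` holds midpoints between
#'   adjacent blocks, used to place new response values.
#' @examples
#' discretize_even_split(c(5, 1, 3, 2, 4, 6), c = 3)$labels  # 3 1 2 1 2 3
#' @export
discretize_even_split <- function(y, c) {
  check_response(y)
  n <- length(y)
  c <- check_bin_count(c, n)
  ord <- order(y)                      # radix sort: stable on ties
  sizes <- split_sizes(n, c)
  labels <- integer(n)
  labels[ord] <- rep.int(seq_len(c), sizes)
  cuts <- NULL
  if (c > 1L) {
    ys <- y[ord]
    cum <- cumsum(sizes)[-c]
    cuts <- (ys[cum] + ys[cum + 1L]) / 2
  }
  new_bin_assignment(labels, c, "even_split", cuts = cuts)
}

#' Equal-frequency discretization
#'
#' Cuts the response at the `i/c` sample quantiles (the values at the
#' even-split block boundaries) with the convention that a sample equal to a
#' cut point goes to the *lower* bin. All duplicates of one value therefore
#' share a bin — ties never straddle a boundary — so bin sizes are only
#' approximately equal when duplicates are present. On a duplicate-free
#' response the assignment is identical to [discretize_even_split()].
#'
#' @inheritParams discretize_random
#' @return a [new_bin_assignment()] object with `cuts` at the bin boundaries.
#' @examples
#' discretize_equal_frequency(c(1, 2, 2, 2, 3, 4), c = 2)$sizes  # 4 2
#' @export
discretize_equal_frequency <- function(y, c) {
  check_response(y)
  n <- length(y)
  c <- check_bin_count(c, n)
  if (length(unique(y)) < c) {
    abort(sprintf(
      "equal-frequency binning needs at least c = %d distinct response values (found %d); a bin would be empty",
      c, length(unique(y))), "ensembin_empty_bin")
  }
  if (c == 1L) return(new_bin_assignment(rep(1L, n), 1L, "equal_frequency"))
  ys <- sort(y)
  cum <- cumsum(split_sizes(n, c))[-c]
  cuts <- ys[cum]
  labels <- rowSums(outer(y, cuts, ">")) + 1L
  new_bin_assignment(labels, c, "equal_frequency", cuts = cuts)
}

#' One-dimensional k-means discretization
#'
#' Clusters the response values with k-means (best of `restarts` seeded
#' initializations by within-cluster sum of squares), then relabels clusters
#' `1..c` in ascending order of center. Samples are assigned to the nearest
#' center (ties to the lower bin), so bins are contiguous response intervals.
#' Because k-means minimizes WCSS, extreme outliers tend to be isolated in
#' small bins of their own.
#'
#' @inheritParams discretize_random
#' @param restarts number of random initializations to try (default 10).
#' @return a [new_bin_assignment()] object; `centers` holds the sorted cluster
#'   centers and `cuts` the midpoints between them.
#' @examples
#' discretize_kmeans(c(1, 2, 10, 11), c = 2, seed = 1)$labels  # 1 1 2 2
#' @export
discretize_kmeans <- function(y, c, seed = NULL, restarts = 10L) {
  check_response(y)
  n <- length(y)
  c <- check_bin_count(c, n)
  uy <- unique(y)
  if (length(uy) < c) {
    abort(sprintf(
      "k-means binning needs at least c = %d distinct response values (found %d); a bin would be empty",
      c, length(uy)), "ensembin_empty_bin")
  }
  if (c == 1L) {
    ba <- new_bin_assignment(rep(1L, n), 1L, "kmeans", seed = seed,
                             centers = mean(y))
    ba$wcss <- sum((y - mean(y))^2)
    return(ba)
  }
  # k-means++-style seeding over the distinct values: subsequent centers are
  # drawn with probability proportional to squared distance from the nearest
  # center already chosen
  kpp_init <- function() {
    ctr <- numeric(c)
    ctr[1L] <- sample(uy, 1L)
    if (c > 1L) {
      for (j in 2:c) {
        d2 <- vapply(uy, function(v) min((v - ctr[seq_len(j - 1L)])^2),
                     numeric(1))
        ctr[j] <- if (sum(d2) > 0) sample(uy, 1L, prob = d2) else sample(uy, 1L)
      }
    }
    ctr
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(max(1L, restarts))) {
      init <- if (length(uy) == c) uy else kpp_init()
      km <- tryCatch(
        stats::kmeans(y, centers = matrix(init, ncol = 1L), iter.max = 300L),
        error = function(e) NULL)
      if (!is.null(km) && (is.null(best) || km$tot.withinss < best$tot.withinss)) {
        best <- km
      }
    }
  })
  if (is.null(best)) {
    abort("k-means discretization failed for every initialization",
          "ensembin_empty_bin")
  }
  centers <- sort(as.numeric(best$centers))
  cuts <- (centers[-c] + centers[-1L]) / 2
  labels <- rowSums(outer(y, cuts, ">")) + 1L  # nearest center, ties lower
  ba <- new_bin_assignment(labels, c, "kmeans", seed = seed, cuts = cuts,
                           centers = centers)
  ba$wcss <- sum((y - centers[labels])^2)
  ba
}

#' Discretize a response with a named method
#'
#' Dispatcher over the four discretizers.
#'
#' @inheritParams discretize_random
#' @param method one of `"random"`, `"even_split"`, `"equal_frequency"`,
#'   `"kmeans"`.
#' @param restarts k-means restarts (ignored by the other methods).
#' @return a [new_bin_assignment()] object.
#' @export
discretize <- function(y, c,
                       method = c("even_split", "equal_frequency", "kmeans",
                                  "random"),
                       seed = NULL, restarts = 10L) {
  method <- match.arg(method)
  switch(method,
         random          = discretize_random(y, c, seed = seed),
         even_split      = discretize_even_split(y, c),
         equal_frequency = discretize_equal_frequency(y, c),
         kmeans          = discretize_kmeans(y, c, seed = seed,
                                             restarts = restarts))
}

#' Assign new response values to fitted bins
#'
#' Places held-out samples into the bins of a fitted [new_bin_assignment()]:
#' value-boundary methods use the stored cut points (a value equal to a cut
#' point goes to the lower bin), k-means uses the nearest center, and the
#' random method draws a fresh seeded equal-as-possible random split — by
#' construction random bins carry no information about the response.
#'
#' @param ba a `bin_assignment`.
#' @param y_new numeric vector of new response values.
#' @param seed seed for the random method (default: derived from the fitted
#'   assignment's seed).
#' @return integer vector of bin indices in `1..c`.
#' @export
assign_bins <- function(ba, y_new, seed = NULL) {
  stopifnot(inherits(ba, "bin_assignment"))
  check_response(y_new)
  n <- length(y_new)
  if (ba$method == "random") {
    seed <- seed %||% if (!is.null(ba$seed)) spawn_seed(ba$seed, "test") else NULL
    perm <- with_seed(seed, sample.int(n))
    labels <- integer(n)
    labels[perm] <- rep.int(seq_len(ba$c), split_sizes(n, ba$c))
    return(labels)
  }
  if (ba$c == 1L) return(rep(1L, n))
  as.integer(rowSums(outer(y_new, ba$cuts, ">")) + 1L)
}
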