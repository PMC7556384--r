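# Independent oracles, deliberately kept free of package internals.

# Exact 1-D k-means by dynamic programming over sorted values: D[k, j] is the
# optimal WCSS of the first j sorted points in k clusters. O(n^2 k).
dp_kmeans_wcss <- function(y, k) {
  ys <- sort(y)
  n <- length(ys)
  S <- cumsum(ys)
  S2 <- cumsum(ys^2)
  seg_cost <- function(i, j) {
    # WCSS of ys[i..j]
    s <- S[j] - if (i > 1) S[i - 1] else 0
    s2 <- S2[j] - if (i > 1) S2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n)
  for (j in 1:n) D[1, j] <- seg_cost(1, j)
  if (k > 1) {
    for (kk in 2:k) {
      for (j in kk:n) {
        best <- Inf
        for (i in kk:j) {
          v <- D[kk - 1, i - 1] + seg_cost(i, j)
          if (v < best) best <- v
        }
        D[kk, j] <- best
      }
    }
  }
  D[k, n]
}

# Rand index between two label vectors: fraction of sample pairs on which the
# two clusterings agree (together/apart).
rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in 1:(n - 1)) {
    sa <- a[i] == a[(i + 1):n]
    sb <- b[i] == b[(i + 1):n]
    agree <- agree + sum(sa == sb)
  }
  agree / (n * (n - 1) / 2)
}

# high-precision R^2 recomputation (sum() in extended precision via Kahan-free
# long-double accumulation that base sum() already uses; kept independent of
# the package's formula layout)
r2_oracle <- function(obs, pred) {
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}
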