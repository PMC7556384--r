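test_that("even split sorts, blocks, and balances", {
  ba <- discretize_even_split(c(5, 1, 3, 2, 4, 6), 3)
  expect_equal(ba$labels, c(3L, 1L, 2L, 1L, 2L, 3L))

  # duplicates are split across the boundary to keep sizes exactly equal
  expect_equal(discretize_even_split(c(2, 2, 2, 2), 2)$sizes, c(2L, 2L))

  # remainder goes to the earliest bins
  expect_equal(discretize_even_split(rnorm(7), 3)$sizes, c(3L, 2L, 2L))

  # ties broken by original index: stable sort
  ba <- discretize_even_split(c(1, 1, 1, 1), 2)
  expect_equal(ba$labels, c(1L, 1L, 2L, 2L))
})

test_that("random discretizer gives equal-as-possible seeded splits", {
  y <- rnorm(10)
  ba <- discretize_random(y, 2, seed = 7)
  expect_equal(sort(ba$sizes), c(5L, 5L))
  expect_equal(discretize_random(y, 2, seed = 3)$labels,
               discretize_random(y, 2, seed = 3)$labels)
  expect_false(identical(discretize_random(y, 2, seed = 3)$labels,
                         discretize_random(y, 2, seed = 4)$labels))
  expect_equal(discretize_random(rnorm(10), 1, seed = 1)$labels, rep(1L, 10))
})

test_that("bin-count validation rejects impossible c", {
  expect_error(discretize_random(rnorm(5), 6, seed = 1),
               class = "ensembin_invalid_bins")
  expect_error(discretize_random(rnorm(5), 0, seed = 1),
               class = "ensembin_invalid_bins")
  expect_error(discretize_even_split(rnorm(3), 4),
               class = "ensembin_invalid_bins")
})

test_that("equal frequency keeps ties together and matches the quantile cut", {
  ba <- discretize_equal_frequency(c(1, 2, 2, 2, 3, 4), 2)
  expect_equal(ba$sizes, c(4L, 2L))          # all three 2s fall in bin 1
  expect_equal(ba$labels, c(1L, 1L, 1L, 1L, 2L, 2L))

  expect_equal(discretize_equal_frequency(1:6, 3)$labels,
               discretize_even_split(1:6, 3)$labels)

  expect_error(discretize_equal_frequency(rep(3, 8), 2),
               class = "ensembin_empty_bin")
  # enough distinct values but a duplicated run still empties a middle bin
  expect_error(discretize_equal_frequency(c(1, 1, 1, 1, 1, 2, 3), 3),
               class = "ensembin_empty_bin")
})

test_that("equal frequency never splits tied values across bins", {
  set.seed(42)
  for (trial in 1:25) {
    n <- sample(10:60, 1)
    y <- sample(1:8, n, replace = TRUE)  # heavy duplication
    c <- sample(2:4, 1)
    ba <- tryCatch(discretize_equal_frequency(y, c), error = function(e) NULL)
    if (is.null(ba)) next
    for (v in unique(y)) {
      expect_length(unique(ba$labels[y == v]), 1L)
    }
  }
})

test_that("all discretizers produce a disjoint exhaustive cover", {
  set.seed(11)
  for (trial in 1:20) {
    n <- sample(8:80, 1)
    c <- sample(1:min(5, n), 1)
    y <- rnorm(n)
    for (m in c("random", "even_split", "equal_frequency", "kmeans")) {
      ba <- discretize(y, c, method = m, seed = trial)
      expect_length(ba$labels, n)
      expect_true(all(ba$labels %in% seq_len(c)))
      expect_true(all(tabulate(ba$labels, c) > 0L))
    }
  }
})

test_that("even-split balance and order-respecting properties hold", {
  set.seed(5)
  for (trial in 1:30) {
    n <- sample(5:120, 1)
    c <- sample(1:min(6, n), 1)
    y <- rnorm(n)
    ba <- discretize_even_split(y, c)
    expect_lte(max(ba$sizes) - min(ba$sizes), 1L)
    for (m in c("even_split", "equal_frequency", "kmeans")) {
      ba <- tryCatch(discretize(y, c, method = m, seed = trial),
                     error = function(e) NULL)
      if (is.null(ba)) next
      expect_true(!is.unsorted(ba$labels[order(y)]),
                  label = sprintf("%s order-respecting (n=%d c=%d)", m, n, c))
    }
  }
})

test_that("equal frequency equals even split on duplicate-free responses", {
  set.seed(8)
  for (trial in 1:25) {
    n <- sample(6:100, 1)
    c <- sample(2:min(6, n), 1)
    y <- rnorm(n)  # continuous: duplicate-free almost surely
    expect_equal(discretize_equal_frequency(y, c)$labels,
                 discretize_even_split(y, c)$labels)
  }
})

test_that("1-D k-means finds the obvious partitions", {
  expect_equal(discretize_kmeans(c(1, 2, 10, 11), 2, seed = 1)$labels,
               c(1L, 1L, 2L, 2L))
  # WCSS-optimal isolation of an outlier
  expect_equal(discretize_kmeans(c(0, 0, 0, 100), 2, seed = 1)$labels,
               c(1L, 1L, 1L, 2L))
  # degenerate single cluster: WCSS is the total sum of squares
  y <- 1:20
  ba <- discretize_kmeans(y, 1, seed = 1)
  expect_equal(ba$wcss, sum((y - mean(y))^2))
  expect_error(discretize_kmeans(rep(1, 5), 2, seed = 1),
               class = "ensembin_empty_bin")
})

test_that("k-means WCSS matches the exact DP solver on small problems", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    n <- sample(8:50, 1)
    c <- sample(2:5, 1)
    y <- rnorm(n, sd = sample(1:5, 1))
    ba <- discretize_kmeans(y, c, seed = s, restarts = 10)
    if (abs(ba$wcss - dp_kmeans_wcss(y, c)) < 1e-9) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("assign_bins places new values consistently with the fit", {
  y <- c(1, 2, 3, 10, 11, 12)
  ba <- discretize_even_split(y, 2)
  expect_equal(assign_bins(ba, c(0, 2.9, 6.6, 50)), c(1L, 1L, 2L, 2L))
  bk <- discretize_kmeans(y, 2, seed = 1)
  expect_equal(assign_bins(bk, c(0, 7, 100)), c(1L, 2L, 2L))
  br <- discretize_random(y, 3, seed = 2)
  lab <- assign_bins(br, rnorm(9), seed = 5)
  expect_equal(sort(tabulate(lab, 3)), c(3L, 3L, 3L))
})
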