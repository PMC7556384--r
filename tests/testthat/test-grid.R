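# small shared grid fixture: two targets, fast learner
grid_sim <- function(seed = 1L) {
  small_sim(seed = seed, n_train = 120, n_test = 60, p = 8, n_targets = 2)
}

test_that("the grid covers cells, records the base case, and is deterministic", {
  sim <- grid_sim(1)
  rep1 <- run_grid(sim$train, sim$test, c_list = c(2, 3),
                   discretizers = c("even_split", "random"),
                   aggregators = c("averaging", "oversample"),
                   learner = fast_learner(30), smote_k = 3, seed = 7)
  expect_s3_class(rep1, "eval_report")
  expect_equal(nrow(rep1$base), 2L)
  expect_equal(nrow(rep1$regression), 2 * 2 * 2 * 2)  # targets x disc x agg x c
  expect_equal(nrow(rep1$errors), 0L)
  # classifier rows only for the weighted aggregator: one per bin
  expect_equal(nrow(rep1$classifiers), 2 * 2 * (2 + 3))
  expect_true(all(rep1$regression$r2 <= 1))

  rep2 <- run_grid(sim$train, sim$test, c_list = c(2, 3),
                   discretizers = c("even_split", "random"),
                   aggregators = c("averaging", "oversample"),
                   learner = fast_learner(30), smote_k = 3, seed = 7)
  expect_identical(rep1$regression, rep2$regression)
  expect_identical(rep1$classifiers, rep2$classifiers)
})

test_that("a c = 1 cell reproduces the base case exactly", {
  sim <- grid_sim(2)
  rep <- run_grid(sim$train, sim$test, c_list = 1,
                  discretizers = "even_split", aggregators = "averaging",
                  learner = fast_learner(30), seed = 3)
  for (t in rep$base$target) {
    cell <- rep$regression[rep$regression$target == t, ]
    expect_equal(cell$r2, rep$base$r2[rep$base$target == t])
    expect_equal(cell$pct_vs_base, 0)
  }
})

test_that("an empty discretizer list yields a base-only report", {
  sim <- grid_sim(3)
  rep <- run_grid(sim$train, sim$test, discretizers = character(0),
                  learner = fast_learner(30), seed = 1)
  expect_equal(nrow(rep$base), 2L)
  expect_equal(nrow(rep$regression), 0L)
})

test_that("failing cells are recorded and the grid continues", {
  sim <- grid_sim(4)
  # a response with only two distinct values cannot be cut into 3
  # equal-frequency bins, but even_split still can
  y <- ifelse(sim$train$y[, 1] > stats::median(sim$train$y[, 1]), 1, 0) +
    sim$train$y[, 1] * 0
  train <- as_dataset(sim$train$x, cbind(g1 = y))
  test <- as_dataset(sim$test$x, cbind(g1 = sim$test$y[, 1]))
  rep <- run_grid(train, test, c_list = 3,
                  discretizers = c("equal_frequency", "even_split"),
                  aggregators = "averaging", learner = fast_learner(30),
                  seed = 2)
  expect_equal(nrow(rep$errors), 1L)
  expect_equal(rep$errors$discretizer, "equal_frequency")
  expect_equal(nrow(rep$regression), 1L)
  expect_equal(rep$regression$discretizer, "even_split")
})

test_that("the report is invariant to target column order", {
  sim <- grid_sim(5)
  swapped_train <- as_dataset(sim$train$x, sim$train$y[, c(2, 1)])
  swapped_test <- as_dataset(sim$test$x, sim$test$y[, c(2, 1)])
  args <- list(c_list = 2, discretizers = "even_split",
               aggregators = "oversample", learner = fast_learner(30),
               seed = 9)
  r1 <- do.call(run_grid, c(list(sim$train, sim$test), args))
  r2 <- do.call(run_grid, c(list(swapped_train, swapped_test), args))
  for (t in c("g1", "g2")) {
    expect_equal(r1$regression$r2[r1$regression$target == t],
                 r2$regression$r2[r2$regression$target == t])
  }
})

test_that("reports are written as tidy CSVs plus a summary", {
  sim <- grid_sim(6)
  rep <- run_grid(sim$train, sim$test, c_list = 2,
                  discretizers = "even_split",
                  aggregators = c("averaging", "undersample"),
                  learner = fast_learner(30), seed = 4)
  dir <- tempfile()
  write_report(rep, dir)
  expect_true(all(file.exists(file.path(dir, c("base.csv", "regression.csv",
                                               "classifiers.csv",
                                               "summary.txt")))))
  back <- utils::read.csv(file.path(dir, "regression.csv"))
  expect_equal(nrow(back), nrow(rep$regression))
  s <- summary(rep)
  expect_equal(nrow(s), 2L)  # two aggregators x one c x one discretizer
  expect_true(all(c("mean_r2", "mean_pct_vs_base") %in% colnames(s)))
})
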