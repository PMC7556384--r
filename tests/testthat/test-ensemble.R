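test_that("weight normalization follows the stated arithmetic", {
  expect_equal(normalize_weights(c(0.2, 0.3, 0.5)), c(0.2, 0.3, 0.5))
  expect_equal(normalize_weights(c(0.4, 0.4, 0.2)), c(0.4, 0.4, 0.2))
  expect_equal(normalize_weights(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(sum(normalize_weights(runif(7))), 1, tolerance = 1e-12)
  expect_error(normalize_weights(c(0.5, 1.2)),
               class = "ensembin_contract_error")
  expect_error(normalize_weights(c(-0.1, 0.5)),
               class = "ensembin_contract_error")
})

test_that("the trivial learner yields the closed-form prediction", {
  # with a mean regressor and constant-probability classifier, the final
  # prediction must equal the unweighted mean of the per-bin response means
  sim <- small_sim(seed = 2, n_train = 90, p = 4)
  y <- sim$train$y[, 1]
  fit <- ensembin(sim$train$x, y, c = 3, discretizer = "even_split",
                  resampling = resampling_spec("none"),
                  learner = learner_mean(prob = 0.3), seed = 1)
  expected <- mean(vapply(1:3, function(b) mean(y[fit$bins$labels == b]),
                          numeric(1)))
  pred <- predict(fit, sim$test$x)
  expect_equal(pred, rep(expected, nrow(sim$test$x)))
})

test_that("prediction breakdown arithmetic matches the weighting rule", {
  sim <- small_sim(seed = 3, n_train = 90, p = 4)
  fit <- ensembin(sim$train$x, sim$train$y[, 1], c = 3,
                  resampling = resampling_spec("undersample"),
                  learner = fast_learner(), seed = 2)
  bd <- predict(fit, sim$test$x, type = "breakdown")
  expect_equal(rowSums(bd$weights), rep(1, nrow(sim$test$x)), tolerance = 1e-9)
  expect_true(all(bd$weights >= 0))
  expect_equal(bd$final, rowSums(bd$predictions * bd$weights))
  # hand-check one sample against normalize_weights
  i <- 5L
  w <- normalize_weights(bd$probabilities[i, ])
  expect_equal(bd$final[i], sum(w * bd$predictions[i, ]))
  # one-hot probabilities select a single regressor exactly
  expect_equal(sum(normalize_weights(c(0, 1, 0)) * c(10, 20, 30)), 20)
  # stated worked example of the weighting rule
  expect_equal(sum(normalize_weights(c(0.5, 0.25, 0.25)) * c(10, 20, 30)), 17.5)
})

test_that("averaging mode skips classifiers and averages predictions", {
  sim <- small_sim(seed = 4, n_train = 90, p = 4)
  fit <- ensembin(sim$train$x, sim$train$y[, 1], c = 3,
                  aggregator = "averaging", learner = fast_learner(), seed = 2)
  expect_null(fit$classifiers)
  bd <- predict(fit, sim$test$x, type = "breakdown")
  expect_equal(bd$final, rowMeans(bd$predictions))
})

test_that("a one-bin ensemble is bit-identical to the base regressor", {
  sim <- small_sim(seed = 5, n_train = 100, p = 6)
  m1 <- ensembin(sim$train$x, sim$train$y[, 1], c = 1,
                 learner = fast_learner(), seed = 11)
  base <- fit_base(sim$train$x, sim$train$y[, 1], fast_learner(), seed = 11)
  expect_identical(predict(m1, sim$test$x), predict(base, sim$test$x))
  bd <- predict(m1, sim$test$x, type = "breakdown")
  expect_true(all(bd$weights == 1))
})

test_that("finals are convex combinations of per-bin predictions", {
  sim <- small_sim(seed = 6, n_train = 120, n_test = 100, p = 6)
  fit <- ensembin(sim$train$x, sim$train$y[, 1], c = 4,
                  resampling = resampling_spec("oversample", k = 3),
                  learner = fast_learner(), seed = 3)
  bd <- predict(fit, sim$test$x, type = "breakdown")
  expect_true(all(bd$final >= apply(bd$predictions, 1, min) - 1e-9))
  expect_true(all(bd$final <= apply(bd$predictions, 1, max) + 1e-9))
})

test_that("fits are deterministic under a fixed master seed", {
  sim <- small_sim(seed = 7, n_train = 90, p = 4)
  f1 <- ensembin(sim$train$x, sim$train$y[, 1], c = 3,
                 resampling = resampling_spec("oversample"),
                 learner = fast_learner(), seed = 5)
  f2 <- ensembin(sim$train$x, sim$train$y[, 1], c = 3,
                 resampling = resampling_spec("oversample"),
                 learner = fast_learner(), seed = 5)
  expect_identical(predict(f1, sim$test$x), predict(f2, sim$test$x))
})

test_that("classifier training sets are balanced under resampling", {
  sim <- small_sim(seed = 8, n_train = 150, p = 5)
  fit <- ensembin(sim$train$x, sim$train$y[, 1], c = 5,
                  resampling = resampling_spec("oversample"),
                  learner = fast_learner(), seed = 4)
  expect_equal(fit$class_counts$n_pos_fit, fit$class_counts$n_neg_fit)
  expect_true(all(fit$class_counts$n_pos_raw < fit$class_counts$n_neg_raw))
})

test_that("fit and predict validate their inputs", {
  sim <- small_sim(seed = 9, n_train = 60, p = 4)
  x <- sim$train$x; y <- sim$train$y[, 1]
  expect_error(ensembin(x, y[-1], c = 2, learner = learner_mean()),
               class = "ensembin_input_error")
  expect_error(ensembin(x[1:5, ], y[1:5], c = 3, learner = learner_mean()),
               class = "ensembin_input_error")
  fit <- ensembin(x, y, c = 2, learner = learner_mean(), seed = 1)
  expect_error(predict(fit, sim$test$x[, 1:2]),
               class = "ensembin_input_error")
  expect_error(predict_one(fit, sim$test$x[1:2, ]),
               class = "ensembin_input_error")
  bd <- predict_one(fit, sim$test$x[1, ])
  expect_length(bd$final, 1L)
  # empty test matrix gives empty output
  expect_length(predict(fit, sim$test$x[0, , drop = FALSE]), 0L)
})

test_that("a fitted model round-trips through save_model / load_model", {
  sim <- small_sim(seed = 10, n_train = 90, p = 4)
  fit <- ensembin(sim$train$x, sim$train$y[, 1], c = 2,
                  learner = fast_learner(), seed = 6)
  path <- tempfile(fileext = ".rds")
  save_model(fit, path)
  back <- load_model(path)
  expect_identical(predict(back, sim$test$x), predict(fit, sim$test$x))
  # refuses foreign files
  other <- tempfile(fileext = ".rds")
  saveRDS(list(a = 1), other)
  expect_error(load_model(other), class = "ensembin_io_error")
})
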