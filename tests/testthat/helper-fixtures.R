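# shared fixture builders; all randomness is seeded per call

fast_learner <- function(trees = 50L) learner_ranger(num_trees = trees)

# a small regime-structured problem for ensemble-level tests
small_sim <- function(seed = 1L, n_train = 150L, n_test = 60L, p = 10L,
                      n_targets = 1L, ...) {
  generate_synthetic(synthetic_spec(n_train = n_train, n_test = n_test, p = p,
                                    n_targets = n_targets, seed = seed, ...))
}

# imbalanced binary classification fixture with well-separated classes
imbalanced_xy <- function(n_pos, n_neg, p = 4L, seed = 1L) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_pos * p, mean = 2), n_pos, p),
             matrix(rnorm(n_neg * p, mean = -2), n_neg, p))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, labels = rep(c(TRUE, FALSE), c(n_pos, n_neg)))
}
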