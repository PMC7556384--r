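Package: ensembin
Title: Binned Ensemble Regression with Classifier-Weighted Aggregation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ensemble regression that exploits the distribution of a
    continuous response. The response is discretized into c bins (random,
    even-split, equal-frequency, or one-dimensional k-means), a regressor is
    trained on each bin's samples and a one-vs-rest classifier on the whole
    training set, and predictions for new samples are the
    classifier-probability-weighted combination of the per-bin regressor
    outputs. Includes random undersampling and SMOTE oversampling for the
    classifier training sets, an evaluation grid with R-squared and
    classification metrics against a single-regressor base case, a seeded
    generator of regime-structured multi-target regression data emulating
    drug-perturbation gene-expression panels, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ranger,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
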