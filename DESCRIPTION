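Package: mtraining
Title: Semi-Supervised Ensemble Learning for Electronic-Nose Gas
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements M-training, a multi-class semi-supervised
    ensemble algorithm generalizing tri-training to M >= 3 base
    classifiers: unlabeled samples are pseudo-labeled when the vote share
    of a classifier's co-classifier committee reaches an agreement
    threshold, and every refit is guarded by a classification-noise-rate
    condition (with randomized sub-sampling) so the injected label noise
    strictly decreases between rounds. Includes the surrounding
    electronic-nose data layer: steady-state feature extraction from
    metal-oxide sensor response curves, CSV feature tables,
    labeled/unlabeled/test splits, pluggable base classifiers (RBF-kernel
    SVM, PLS-DA, RBF network, nearest centroid), accuracy/improvement
    metrics, an experiment harness, and a synthetic sensor-data generator
    so the full pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    ggplot2,
    generics,
    withr,
    e1071,
    MASS,
    stats
Suggests:
    mixOmics,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
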