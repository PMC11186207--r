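Package: puconfide
Title: Permutation-Test Confidence for Positive-Unlabeled Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Assesses whether a transductive positive-unlabeled (PU)
    classification result could have arisen by chance. Implements PU
    bagging with out-of-bag vote aggregation, K-fold spy-positive scoring
    of the known-positive set (explicit positive recall and mean bagging
    score), a label-permutation null distribution, and comparison
    statistics (upper-tailed z-score, Cliff's Delta with confidence
    interval, and ROC-AUC of the unlabeled set against held-out ground
    truth). Includes a synthetic two-class data generator with
    controllable hypercube class separation for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
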