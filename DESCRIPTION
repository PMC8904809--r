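Package: hetdti
Title: Drug-Target Interaction Prediction from Heterogeneous Association
    Features with Residual Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts drug-target interactions (DTIs) for unseen drugs by
    integrating heterogeneous drug- and protein-related association vectors
    (drug-drug interactions, drug-side-effect, drug-disease, protein-protein
    interactions, protein-protein similarity, and protein-disease
    associations) with pre-trained molecular and protein-sequence embeddings.
    Feed-forward imputer networks complete the association vectors of drugs
    absent from training via zero-masked inputs, and a layer-normalized
    residual network with a sigmoid classifier scores drug-protein pairs.
    Includes the cold-start (drug-based) ten-fold cross-validation protocol
    with per-drug negative sampling, pair-based random cross-validation,
    redundancy filtering of test drugs, frequency-rule baselines, an
    evaluation suite (ROC/PR AUC, precision/recall/F1, per-drug analyses,
    fold-wise significance tests), and a synthetic-data generator with
    planted latent structure so the entire pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
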