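Package: somkit
Title: Site-of-Metabolism Prediction from 2D Topological Circular Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts cytochrome P450 sites of metabolism (SoMs) in small
    molecules from purely 2D structure. Atomic sites are encoded as circular
    fingerprints counting SYBYL atom types in concentric bond-distance shells,
    and classified by three probabilistic learners - Naive Bayes, the
    Parzen-Rosenblatt window (Gaussian kernel density) and RASCAL (a Dirac,
    exact-match kernel) - each run as a random feature-subspace voting
    ensemble. Includes TRIPOS mol2 input, molecule-level leave-one-out
    cross-validation with symmetry-equivalent site collapsing, ranked
    predictions with MCC, ROC/AUC and top-k metrics, a similarity-based
    applicability-domain split, and a synthetic corpus generator with a
    plantable local-motif signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
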