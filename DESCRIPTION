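Package: CodeSieve
Title: Unsupervised Feature Selection for Hierarchical Clinical Code Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Selects informative features from sparse one-hot encodings of
    hierarchical medical code data (ICD-10 style diagnosis trees and ATC drug
    classification codes). Implements five unsupervised selector families --
    Laplacian score, multi-cluster feature selection, autoencoder-inspired
    selection, principal feature analysis, and concrete autoencoders with an
    optional depth-based loss weighting that steers selection toward general
    codes -- together with two evaluation tracks: reconstruction of the full
    feature space against a mode baseline, and imbalanced binary outcome
    prediction with gradient-boosted trees, DeLong and McNemar comparisons,
    and tree Shapley importances. Ships a synthetic-data generator that
    emulates the record structure of administrative health databases so the
    whole pipeline runs without access to protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    xgboost,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
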