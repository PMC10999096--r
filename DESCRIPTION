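Package: mlscreen
Title: Target-Specific Machine-Learning Scoring Functions for Structure-Based Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and benchmarks target-specific machine-learning scoring
    functions for structure-based virtual screening. Provides bioactivity
    curation with assay-aware train/test splitting, featurization of docked
    protein-ligand poses (protein-ligand extended connectivity fingerprints,
    grid-based interaction features, and ligand-only Morgan fingerprints),
    five supervised learning algorithms in classification and regression
    modes with tree-structured Parzen estimator hyperparameter tuning, and
    early-enrichment evaluation (EF1%, NEF1%, precision-recall curves,
    dissimilar-test-set stress testing and hit clustering). A seed-controlled
    synthetic fixture generator makes the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    bio3d,
    ChemmineR,
    ChemmineOB,
    randomForest,
    xgboost,
    e1071,
    nnet
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
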