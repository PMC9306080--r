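Package: hitstack
Title: Two-Stage Virtual Screening with Stacked Ensembles and
    Interaction-Count Rescoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies bioactivity hits with a chemical-space stacked
    ensemble (random forest and gradient-boosting base learners whose
    out-of-fold predictions train a neural-network super learner) and
    optimizes them in protein space: a deep network trained on
    substructure-count fingerprints is fused with per-complex
    protein-ligand interaction counts into a ranking score, filtered by a
    target-specific interaction-count window.  Includes descriptor
    preprocessing filters (sparsity, low variance, correlation), a
    geometric protein-ligand interaction profiler for docked PDB
    complexes, evaluation metrics (balanced classification rate, ensemble
    diversity entropy, rank-based AUC), and synthetic data generators for
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    xgboost,
    bio3d,
    igraph,
    jsonlite,
    ChemmineR,
    ChemmineOB,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
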