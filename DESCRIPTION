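Package: aladdin
Title: Machine-Learning-Guided Protein Structure Selection for
    Docking-Based Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Implements ALADDIN, a structure-selection strategy for
    docking-based virtual screening against conformational ensembles of a
    protein target.  A battery of per-structure random-forest classifiers
    is trained to predict, from a compound's 2D fingerprint, whether a
    given docking protocol will rank that compound correctly on a given
    protein structure; each query compound is then docked only against
    the structure with the highest predicted correctness probability.
    The package ships the comparator protocols (single-structure docking,
    all-against-all ensemble docking, similarity-based structure
    selection), rank-based correctness labeling, hashed circular
    fingerprints and Tanimoto similarity, a virtual-screening evaluation
    stack (ROC/AUC, enrichment factors, Matthews correlation,
    Y-scrambling), and a seeded synthetic docking-score simulator with
    planted compound-structure compatibility so that the full method is
    testable without a docking engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    ChemmineOB,
    ChemmineR,
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
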