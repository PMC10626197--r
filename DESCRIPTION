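Package: synergyloop
Title: Sequential Model Optimization for Drug Combination Synergy Discovery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering synergistic drug pairs with sequential
    model optimization. Computes elementwise and pooled Bliss synergy scores
    from replicate dose-response matrices with plate normalization and
    quality-control filters, builds drug feature matrices from circular
    fingerprints and one-hot encodings, and fits a permutation-invariant
    regression model (MLP drug encoder, symmetric bilinear combination
    module, FiLM cell-line conditioning) with deep-ensemble or direct
    uncertainty estimation. Batches of candidate combinations are selected
    with greedy, pure-exploration or upper-confidence-bound acquisition under
    per-drug constraints, and an iterative query/retrain loop is provided
    together with an evaluation harness (out-of-distribution splits,
    enrichment curves, replicate-noise performance bounds) and a synthetic
    synergy-landscape generator for end-to-end simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    cluster,
    jsonlite,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Cheminformatics, Regression, MachineLearning, Pharmacogenomics
RoxygenNote: 7.3.3
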