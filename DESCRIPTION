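Package: mechanonps
Title: Single-Cell Mechanophenotyping, Mechanical Age Classification and
    Risk Scoring for Mechano-Node-Pore Sensing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mechano-node-pore sensing (mechano-NPS), a microfluidic
    resistive-pulse platform that measures the size, deformability and
    post-deformation recovery of single cells. Provides a phenomenological
    simulator of current traces and cell populations, sub-pulse extraction
    from current-versus-time recordings, the device physics linking current
    blockades to free cell diameter, transverse deformation and the
    whole-cell deformability index (wCDI), a ten-feature design matrix with
    Yeo-Johnson normalisation, the MechanoAge stacked tree-ensemble age
    classifier (bagged trees, random forest and extremely randomised trees
    combined by a gradient-boosted meta-learner), the Mechano-RISQ deviation
    score with Crawford-Howell single-case inference, and a mass-cytometry
    analysis layer (differential marker expression and frozen-model
    signature transfer with DeLong comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    caret,
    car,
    pROC,
    randomForest,
    ranger,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
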