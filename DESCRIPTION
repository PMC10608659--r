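Package: quinoscreen
Title: QSPR Screening of Quinone Redox Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for structure-based screening of quinone
    organic electrode materials. Enumerates -CN and -C#CMe derivatives of
    quinone scaffolds with symmetry-aware deduplication, computes a panel of
    topological and electrotopological (E-state) molecular descriptors with a
    Hueckel pseudo-LUMO surrogate, converts species thermochemistry to redox
    potentials via the Nernst equation, performs multi-stage descriptor
    selection (low-variance, target-correlation, mutual-correlation, backward
    stepwise by cross-validated R-squared), and compares five regression
    models (ridge closed form, CART, random forest, extra trees, gradient
    boosting) implemented from their defining equations. A synthetic-data
    generator emulating the statistical structure of DFT-derived redox labels
    makes every stage testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    rpart,
    randomForest,
    ranger,
    xgboost,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
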