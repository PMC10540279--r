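Package: stereonn
Title: Enantioselectivity Prediction from Transition-State Descriptors
    with Small-Data Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Predicts the enantiomeric ratio of an asymmetric,
    Pd-catalysed Negishi cross-coupling from geometric descriptors of
    diastereomeric transition-state structures. Parses XYZ geometries and
    computes descriptors of the trigonal Pd coordination environment
    (out-of-plane displacement, deviation from an ideal Y-shape,
    projected-metal angle, bond lengths and angles); converts losslessly
    among five selectivity encodings (ee, er, ln er, S%, R%) and between
    er and the transition-state free-energy difference via the Boltzmann
    relation; assembles per-ligand feature tables with min-max
    normalization and manual, PCA or Sammon-mapping dimensionality
    reduction; trains a small feed-forward neural network under
    leave-one-out cross-validation; and provides an anti-overfitting
    battery (Y-shuffling, X/Y-randomization), a five-metric model
    bake-off, and a pure free-energy baseline. Synthetic generators for
    planted-signal feature tables and toy trigonal Pd complexes make
    every stage testable without quantum-chemistry software.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
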