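Package: betaturn
Title: Beta-Turn Assignment and Two-Layer Neural-Network Prediction from
    Sequence Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Geometric assignment of beta-turns and their nine types from
    protein backbone coordinates (7 Angstrom C-alpha rule, phi/psi dihedral
    classification with circular tolerances, cis-proline handling, type IV
    catch-all), sliding-window encoding of sequence profiles together with
    predicted secondary structure and relative surface accessibility, a
    two-layer ensemble of feed-forward neural networks (general,
    position-specific and type-specific predictors) trained by
    cross-validation with MCC-based epoch selection, residue-level
    evaluation (MCC, Q_total, PPV, sensitivity, specificity, ROC/AUC,
    threshold sweeps, AUC-difference tests), dataset construction tools
    (chain ranking, pairwise identity, Hobohm-1 homology reduction,
    composition statistics), and a fully seeded synthetic-fixture generator
    that builds backbone chains with planted turns and label-correlated
    profile tracks so the whole pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    withr,
    ggplot2,
    generics,
    stats,
    utils,
    bio3d,
    Biostrings,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
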