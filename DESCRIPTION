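Package: hybridfold
Title: RNA Secondary Structure Prediction with Thermodynamic and Learned
    Folding Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts pseudoknot-free RNA secondary structures by exact
    Zuker-style dynamic programming over a hybrid scoring function that adds
    neural-network folding scores (helix stacking, helix opening, helix
    closing, unpaired region) to a reduced Turner nearest-neighbor free
    energy model.  The network is trained with a structured max-margin
    objective that includes a thermodynamic regularizer keeping learned
    scores close to the negated free energy.  Includes readers and writers
    for FASTA, BPSEQ, CT and dot-bracket formats, base-pair accuracy and
    energy-correlation metrics, and a synthetic sequence/structure/energy
    generator for training and benchmarking without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
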