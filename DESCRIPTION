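Package: modfoldkit
Title: Hybrid Per-Residue and Global Quality Estimation for Protein 3D Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the local (per-residue) and global accuracy of predicted
    protein tertiary structure models using a hybrid of pure-single model scores
    (contact-distance agreement against predicted residue contacts, secondary
    structure agreement) and quasi-single model scores computed against a
    reference model ensemble (superposition-based S-scores, superposition-free
    Q-scores, disorder/fluctuation agreement). Per-residue score tracks from
    thirteen methods are combined through a windowed single-hidden-layer neural
    network trained against observed S-score or lDDT targets; predicted
    similarities are converted to Angstrom Calpha error estimates via the
    inverse S-score function. Includes observed-quality oracles (S-score with
    iterative superposition, lDDT), CASP QA format output, b-factor annotated
    models, confidence tiers with empirical P-values, and a deterministic
    synthetic benchmark generator for training and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    nnet,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
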