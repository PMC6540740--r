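Package: mpsfold
Title: RNA Secondary Structure Prediction by Pairing-Matrix Encoding and
    Maximum-Probability-Sum Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts nested RNA secondary structures from sequence alone.
    Each sequence is encoded as a Gaussian-weighted base-pairing matrix in
    which contiguous stems appear as strong anti-diagonal signals; a small
    convolutional network classifies every base into one of the three
    dot-bracket labels "(", ")" and "."; and a Nussinov-style dynamic
    program decodes the per-base label probabilities into the valid nested
    structure with the maximum summed label probability. Includes readers
    and writers for FASTA, CT, BPSEQ and dot-bracket files, dataset
    preparation utilities (pseudoknot filtering, redundancy removal,
    stratified splitting), base-pair-level evaluation (sensitivity,
    PPV, F-score), a synthetic sequence/structure generator for end-to-end
    testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    Biostrings
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
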