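Package: sncscan
Title: Small Non-Coding RNA Locus Discovery by Multi-Branch Convolutional Scanning
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Locates small non-coding RNA loci (pre-miRNA-like hairpins, snoRNAs)
    in genomic regions by sliding a multi-branch convolutional classifier over
    candidate windows. Each enabled branch consumes one feature block of a
    100-bp window: one-hot DNA sequence, one-hot dot-bracket secondary
    structure, and raw per-base evolutionary conservation. Training uses an
    iterative background-selection scheme: an ensemble of models trained
    against random length-matched negatives scans large regions, consensus
    false positives ("hard cases") are harvested, and the best ensemble member
    is retrained on the enhanced negative pool. Includes strand-aware BED
    interval arithmetic, a base-pair-maximizing folding fallback, scanning and
    pre-labelled evaluation with the 50-percent-overlap hit rule, and a
    synthetic-genome benchmark generator with planted hairpin loci.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    Rcpp,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    GenomicRanges,
    IRanges,
    rtracklayer
LinkingTo: Rcpp, RcppArmadillo
Config/testthat/edition: 3
RoxygenNote: 7.3.3
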