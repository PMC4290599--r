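Package: g4hmm
Title: Hidden Markov Models for DNA G-Quadruplex Motif Detection and Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Probabilistic detection and screening of DNA G-quadruplex (G4)
    motifs. Provides four hidden Markov model topologies over alternating
    G-run and loop blocks, trained by Baum-Welch expectation-maximization and
    decoded by the Viterbi algorithm; log-odds scoring against an i.i.d. base
    background with collection-level Z-score standardization and
    normal-quantile screening cutoffs; a regular-expression prefilter for
    genome-scale scanning of putative G4 motifs; trinucleotide (order-2
    Eulerian) shuffling for negative controls; per-base G-run prediction
    metrics, cross-validation and ROC analysis; and per-gene G4-density
    statistics. Includes seeded synthetic-sequence generators so the full
    pipeline is testable without external genome or database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
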