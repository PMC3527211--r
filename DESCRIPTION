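Package: invgen
Title: Age, Origin, and Selection Analyses for Chromosomal Inversion
    Polymorphisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Population-genomic analyses of paracentric inversion
    polymorphisms from breakpoint-proximal sequence alignments: rejection
    approximate Bayesian computation (ABC) age estimation under an
    exponential-growth coalescent, divergence-based ages, geographic-origin
    classification against African and cosmopolitan reference panels,
    detection and masking of genetic-exchange tracts between arrangements,
    nucleotide diversity and Hudson F_ST scans, breakpoint-gene permutation
    tests, sex-ratio distortion statistics for cross progeny counts, and
    consensus-quality arithmetic (Poisson error bounds, Phred conversion,
    depth-titration bootstraps). Includes a synthetic-data generator that
    emulates the assumed data structure (inverted clade nested in a diverse
    African standard sample plus a bottlenecked cosmopolitan sample) with
    ground-truth ledgers, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
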