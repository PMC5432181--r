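Package: dealr
Title: Error-Compensated Diversity Estimation for Antibody Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the complexity (diversity) of antibody libraries from
    paired-end Illumina sequencing while compensating for technical sequencing
    error. Implements quality-aware sequence-identity collapse (DEAL): reads are
    partitioned by a CDR3 seed, then merged by flag-aware binary comparison where
    positions with low Phred quality or a high Phi-X-measured cycle error rate are
    treated as unreliable and resolved with IUPAC ambiguity codes. Provides
    per-cycle error profiling from Phi-X spike-in reads, complexity bounds and a
    truncated negative-binomial estimate of total library complexity, in-silico
    translation with frameshift and stop-codon accounting for protein-level
    diversity, primer-class assignment with chain-assortment diagnostics, and a
    synthetic paired-end read simulator with full truth tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    minpack.lm,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
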