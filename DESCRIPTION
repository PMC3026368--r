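Package: dyadscan
Title: Genome-Wide Detection and Enrichment of Hairpin-Forming Inverted Repeats
Version: 1.0.0
Authors@R:
    person("dyadscan", "maintainers", email = "dyadscan@example.org", role = c("aut", "cre"))
Description: Scans genomic DNA for partially symmetric inverted repeats by locally
    aligning multi-scale sliding windows against their own reverse complements with a
    wobble-aware scoring scheme, then enriches the candidates for pre-miRNA-like
    hairpins using four quantitative filters: pairing density, binomial occurrence
    probability of the observed symmetry, mean contiguous stem length, and stem GC
    content. Includes duplicate removal across overlapping windows, validation of
    candidate sets against known precursor sequences, an automated parameter-tuning
    loop, and a synthetic-genome simulator that plants degraded hairpins with truth
    annotations for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    optparse,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
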