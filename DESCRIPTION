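Package: codonqueue
Title: Stochastic Ribosome Traffic Simulation and In Silico tRNA Depletion Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates mRNA translation as a totally asymmetric simple
    exclusion process (TASEP) with extended 9-codon ribosomes and two-state
    elongation kinetics (codon-specific tRNA arrival followed by
    translocation), using a continuous-time Gillespie algorithm. Builds
    per-codon tRNA-arrival rates from tRNA gene copy numbers, applies in
    silico tRNA depletions, and screens transcriptomes for mRNAs whose
    translation rate is sensitive to the depletion. Includes an exact
    stationary-state Markov-chain oracle for small lattices, initiation-rate
    scans, ribosome-density profiling, synonymous codon swapping, rare-codon
    composition statistics, and a synthetic-fixture generator so every
    analysis is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
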