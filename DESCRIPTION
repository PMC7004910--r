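Package: armcompare
Title: Comparative Analysis Toolkit for a Polyploid Chromosome Arm and Its Diploid Donor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reusable implementations of the computations behind a
    chromosome-arm comparative genomics study: closing assembly N-gaps from
    filler-sequence pools with a built-in seed-and-extend local aligner,
    reciprocal-best-hit orthology and a donor-versus-polyploid gene-loss
    classification cascade, Nei-Gojobori dN/dS scanning with codon-usage-bias
    features (ENC, CAI), exact 2x2 category-enrichment statistics with
    Benjamini-Hochberg control, LTR retrotransposon insertion dating from
    paired-LTR divergence, and electronic-PCR marker and QTL anchoring. A
    synthetic-data module simulates a chromosome arm with genes, LTR elements,
    planted gaps, filler pools and markers, with full truth tables, so every
    stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
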