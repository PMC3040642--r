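Package: barcodeaudit
Title: Quality Audit of DNA Barcode Reference Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing species-level COI DNA barcode reference
    libraries. Computes Kimura 2-parameter pairwise distances with pairwise
    deletion of ambiguous sites, summarises intraspecific and interspecific
    divergence, performs nearest-neighbour barcode-gap analysis, detects
    barcode sharing between species and deep intraspecific splits, and builds
    neighbour-joining cluster trees. Includes a sequence-evolution simulator
    that generates barcode libraries with known structure and injected
    anomalies, so every stage of the audit can be exercised against a ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    ape,
    Biostrings,
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
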