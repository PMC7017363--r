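Package: tadlink
Title: Linking Differentially Methylated Regions to Genes via Consensus
    Topologically Associating Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build consensus maps of topologically associating
    domains (TADs) conserved across cell types, test the placement of
    differentially methylated regions (DMRs) relative to those domains
    with composition-matched Monte Carlo nulls, assign non-genic DMRs to
    genes by linear and anchor-mediated spatial distance, and test the
    resulting gene list for body-part enrichment against a user-supplied
    gene-to-organ annotation table. Includes a synthetic-data generator
    with planted ground truth so every stage of the pipeline can be
    validated without external downloads. All user-facing functions take
    data frames and return tibbles, so analyses compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
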