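Package: culturoscope
Title: Culturomics by Double-Barcoded 16S rRNA Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for analysing bacterial cultivation
    experiments with barcoded 16S rRNA gene amplicon sequencing. Implements
    double-barcode demultiplexing for the identification of individually
    picked colonies, quality filtering with explicit per-rule accounting,
    open-reference greedy OTU clustering at 97% identity with centroid
    representatives, majority-rule colony-to-OTU assignment, explicit
    growth-detection criteria for plate-scraped communities (designed to
    reject inoculum carry-over), taxonomic novelty classification against
    type strains, and the supporting community statistics (Shannon
    diversity, rarefaction, Bray-Curtis dissimilarity, UPGMA clustering and
    SIMPER decomposition). A seeded synthetic-data generator emulates
    454-style amplicon sequencing of plated sponge bacterial communities so
    the whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
LinkingTo: Rcpp
Suggests:
    ape,
    biomformat,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
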