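Package: ampliclean
Title: Replicate-Aware Stringency Filtering for Amplicon and Metagenomic Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cleaning and comparing marine microbiome survey data
    sequenced in PCR replicates. Implements a cascade of stringency filters
    (singleton removal per replicate, minimum-copy thresholds across
    replicates) on OTU count tables, aggregation of OTUs into phylotypes at
    the lowest assigned taxonomic rank, BLAST top-hit taxonomy assignment for
    size-fractionated metagenomes with curated viral lineages, presence-absence
    comparisons between size fractions and annotation methods, Krona text
    export, and a seeded mock-community generator so that every stage of the
    pipeline can be exercised without external sequencing data.
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
    stringr,
    tibble,
    tidyr,
    withr
LinkingTo: Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
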