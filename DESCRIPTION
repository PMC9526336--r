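Package: nahrburden
Title: Recessive Disease Burden from NAHR-Mediated Recurrent Genomic Deletions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a genome-wide map of recurrent genomic deletions mediated by
    nonallelic homologous recombination (NAHR) between directly oriented
    segmental duplications, assembles per-gene recessive carrier-allele pools
    from ClinVar-style and gnomAD-style variant tables, and quantifies the
    deletion allele's contribution to autosomal recessive disease burden with a
    Punnett-square model under random mating. Implements the fraction of allele
    burden (Fa), fraction of disease burden (Fd), per-allele odds, the NIRD and
    AIRD log2 odds-ratio scores, population-specific delta-NIRD, expected
    biallelic-configuration distributions for patient cohorts, and a seeded
    synthetic-data generator so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    igraph,
    generics,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
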