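Package: consensusref
Title: Consensus Reference Genomes from Cohort Variant Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds major-allele consensus references (all-cohort and
    population-specific) from cohort variant data, re-expresses personal
    genotypes against them, and quantifies how the number and
    allele-frequency spectrum of called variants changes relative to a
    conventional single-haplotype ("type specimen") reference. Includes a
    synthetic-cohort generator (Hardy-Weinberg genotypes, Balding-Nichols
    population structure, configurable site-frequency spectrum) so the whole
    analysis is testable without external genotype downloads, plus VCF/FASTA
    input-output, haploid collapsing of diploid genomes, per-sample variant
    summaries, and cumulative allele-frequency reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
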