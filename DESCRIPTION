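Package: gwasrx
Title: GWAS-Driven Drug Repurposing Screens and Case-Control Association Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for genome-wide association study (GWAS)
    follow-up analyses. Implements single-SNP case-control association
    statistics from genotype-count tables (minor allele frequency, the
    Cochran-Armitage trend test, the genotypic 2x3 chi-squared test, the exact
    Hardy-Weinberg equilibrium test, allelic odds ratios with Wald confidence
    intervals, call rates, two-locus linkage-disequilibrium r-squared, and
    inverse-variance fixed-effects meta-analysis), together with a
    network-based in silico drug-repurposing screen that expands risk genes by
    direct protein-protein-interaction neighbors and intersects them with
    approved-drug target genes. A synthetic-data module simulates case-control
    genotype counts under an additive allelic-odds disease model and builds
    planted screen instances with known truth, so every pipeline stage is
    testable without external databases. Plain TSV readers and writers and a
    thin command-line interface tie the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
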