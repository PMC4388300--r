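Package: divscan
Title: Windowed Genome Divergence Scans, Divergence Islands, and
    Coalescent Simulation for Hybridizing Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying genome-wide divergence between closely
    related, hybridizing populations. Computes windowed population-genetic
    statistics (AMOVA-style F_ST, nucleotide diversity, d_XY, Tajima's D,
    derived allele frequency, fixed-difference fraction, linkage
    disequilibrium r^2, and the ABBA-BABA Patterson's D) from multi-sample
    VCFs; segments F_ST tracks into divergence islands with an empirical
    percentile linking rule; performs bootstrap and permutation inference
    on divergent versus background windows, chromosome clustering and
    enrichment tests; simulates data under a structured coalescent with
    migration parsed from ms-style command lines; and fits linear versus
    exponential models of divergence growth over time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
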