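Package: lektimap
Title: Genotype-Phenotype Mapping of SPINK5 Variants onto LEKTI Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for genotype-phenotype analysis of Netherton syndrome
    cohorts. Parses HGVS cDNA variant descriptions on the SPINK5 reference
    transcript NM_006846.4, maps each allele onto the 15 Kazal-type domains
    and 5 bio-reactive domain regions of the LEKTI protein, codes biallelic
    genotypes into numeric covariates (transcript-half, domain-number and
    indicator products), and fits binary logistic regressions with an age
    covariate to estimate odds ratios for nine tri-state clinical
    phenotypes. Includes a contingency-table analysis of infant mortality
    in homozygous carriers of fatal variants, curation filters for cohort
    tables, and a seeded synthetic-cohort simulator for power and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
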