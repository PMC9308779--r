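Package: clonehema
Title: Detection of Clonal Hematopoiesis from Paired Blood/Tumor Somatic Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering clonal hematopoiesis (CH) in cancer
    cohorts from "reverse" somatic variant calls, where the blood sample is
    treated as the tumor and the solid tumor as the germline reference. The
    package implements the post-calling filter cascade that turns raw
    blood-vs-tumor calls into somatic mutation catalogs, SBS96 mutational
    signature construction and bootstrapped NMF extraction with exposure
    refitting, classification of CH cases by driver-gene mutations and by the
    rate of hematopoiesis mutations per year of age, logistic-regression
    associations with age, sex and treatment, and scanning of non-coding
    variants for transcription-factor binding-site disruption or creation.
    A synthetic-cohort generator emulates the statistical structure of paired
    blood/tumor cohorts so the whole pipeline is testable without protected
    patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    broom,
    generics,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
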