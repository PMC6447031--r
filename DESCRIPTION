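Package: sepsisldl
Title: Confounder-Adjusted Association of LDL Cholesterol with Sepsis Risk
    from Electronic Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for asking whether low LDL
    cholesterol directly increases the risk of sepsis among patients
    admitted to hospital with infection, or whether the apparent risk is
    confounded by comorbid illness.  Provides rule-based identification of
    infection episodes from coded billing data, Sepsis-3-style sepsis
    phenotyping from explicit codes and five organ-dysfunction criteria,
    baseline (pre-illness) LDL qualification, Charlson/Deyo comorbidity
    covariates mapped through PheCode groupings, a weighted-allele LDL
    genetic risk score, and logistic association models reporting odds
    ratios per standard deviation and by quartile.  A synthetic
    longitudinal health-record generator with a configurable confounding
    structure makes every stage testable without access to protected data.
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
    generics,
    yaml,
    stats,
    utils
Suggests:
    vcfR,
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
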