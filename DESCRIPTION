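Package: hbmtier
Title: Tiered Human-Biomonitoring Risk Assessment for Pyrethroid Insecticides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives urinary human-biomonitoring guidance values (HBM-GVs) for
    pyrethroid insecticides from external health-based guidance values (ADIs)
    through a steady-state mass-balance equation, and runs a tiered risk
    assessment against aggregated urinary biomarker surveys: conservative
    screening on the common metabolites 3-PBA and 4-FPBA, substance-specific
    risk characterisation ratios, a combined-mixture refinement using
    ADI-ratio relative potencies, and probabilistic (Monte Carlo) refinements
    of both the guidance values and the population exceedance probability.
    Ships a registry of substances, metabolites and molar urinary excretion
    fractions, a percentile-table exposure reader, distribution utilities
    (log-logistic, Weibull, triangular) with quantile-based fitting, and a
    synthetic cohort generator for end-to-end validation.
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
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
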