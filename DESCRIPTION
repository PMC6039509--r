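Package: ednariver
Title: Quantitative Analysis of River eDNA Metabarcoding Fish Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for quantitative analysis of
    environmental DNA (eDNA) metabarcoding surveys of river fish
    assemblages. Standardizes site-by-MOTU read tables by rarefaction,
    fits binomial-logit models of PCR detection rate against log read
    count and inverts them to relative abundance at target detection
    rates, compares eDNA assemblages with capture (electrofishing)
    surveys through diversity indices and paired non-parametric tests,
    couples the two descriptions with centered PCA and co-inertia
    analysis (RV coefficient with permutation test), quantifies
    longitudinal spatial structure with Mantel correlograms of
    Bray-Curtis dissimilarity, and predicts downstream eDNA detection
    distances from channel hydraulics with a fine-particulate-matter
    deposition-velocity transport model. A seeded synthetic-data
    generator reproduces the statistical structure of such surveys so
    the whole pipeline is testable offline.
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
    vegan,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
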