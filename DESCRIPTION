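Package: mitoscreen
Title: Multiparametric Mitochondrial Toxicity Screening with Kinetic
    OCR/ECAR Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for plate-based mitochondrial
    toxicity screening built around kinetic oxygen-consumption (OCR) and
    extracellular-acidification (ECAR) assays. Provides a synthetic-data
    generator for intact-cell mitostress and permeabilized-cell
    electron-transport-chain (ETC) complex assays, the associated
    normalization ledger (baseline, vehicle, non-effective-concentration and
    glycolytic-range scaling), decomposition of mitostress traces into
    basal, ATP-linked, maximal, proton-leak and non-mitochondrial
    respiration, rule-based ETC complex-specificity calls, censored
    four-parameter Hill potency estimation with Dunnett-based
    lowest-observed-effect concentrations, and cross-assay integration into
    a compound-by-endpoint summary matrix with mechanism-of-action calls.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    minpack.lm,
    multcomp,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
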