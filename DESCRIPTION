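Package: rrfquant
Title: Relative-Response-Factor Quantification and Validation of
    Procyanidin Oligomers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies monomeric and oligomeric procyanidins (degree of
    polymerisation 1 to 10) from integrated fluorescence peak responses
    using relative response factors (RRFs) against an epicatechin
    calibration, and computes the accompanying method-validation
    statistics: calibration linearity with a lack-of-fit test and a
    forced-through-zero decision, limits of quantification, repeatability
    and intermediate precision by one-way ANOVA, spike recovery, bias
    against a certified reference material, a combined expanded
    measurement uncertainty budget, stability acceptance, and
    inter-laboratory consensus statistics with z-score evaluation. A
    synthetic-data module generates detector data with the variance
    structure the analysis assumes so the whole pipeline is testable
    end to end.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
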