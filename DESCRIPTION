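Package: hazeimpact
Title: Health and Economic Impact Assessment of Fine Particulate Pollution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end assessment pipeline for the health and economic
    burden of fine particulate (PM2.5) pollution. Concentrations are forecast
    with a grey GM(1,1) model whose residuals are corrected by a Markov state
    chain with genetic-algorithm-optimised whitening coefficients; attributable
    deaths and disease cases follow from exposure-response functions with
    confidence-interval propagation; the resulting labor loss and excess
    medical expenditure shock a social-accounting-matrix-calibrated recursive
    dynamic computable general equilibrium model of a closed regional economy.
    Ships the Beijing 2013-2020 study inputs as plain-text fixtures and
    synthetic-data generators for every pipeline stage.
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
    tibble,
    tidyr,
    withr,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
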