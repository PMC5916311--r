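Package: phytocomp
Title: Growth, Competition and Carbonate Chemistry for Phytoplankton CO2 Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multispecies phytoplankton culture experiments
    under contrasting CO2 levels: simulation of batch and semicontinuous culture
    experiments with realistic counting noise, exponential growth-rate estimation
    with dilution correction, predicted and realized competition coefficients
    from pure-culture rates and mixture frequency dynamics, regressions testing
    whether growth responses to CO2 predict competitive and community responses,
    and a seawater carbonate-system solver (pH/alkalinity to DIC and pCO2) for
    quantifying culture CO2 drawdown.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
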