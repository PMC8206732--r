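Package: wheatclim
Title: Climate-Change Risk Analysis for Winter Wheat with a Process-Based
    Simulator and Stochastic Weather Generator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for assessing climate-change impacts on
    winter wheat yields. Couples a seeded stochastic daily weather generator
    (first-order Markov precipitation occurrence with gamma amounts, AR(1)
    temperature residuals, clearness-index solar radiation) with a simplified
    daily-timestep wheat simulator (thermal-time phenology with vernalization
    and photoperiod, radiation-use-efficiency biomass accumulation with CO2
    fertilization, layered soil-water balance with a moisture choking
    function, and grain-set reduction from drought or heat around flowering).
    Computes water, drought and heat stress indices from four paired
    simulation runs, percentile-based risk metrics with recurrence intervals,
    yield coefficient of variation, and multi-site, multi-scenario ensemble
    summaries with boxplot statistics and loss-frequency curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
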