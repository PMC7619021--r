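Package: ringclim
Title: Dendroclimatic Water-Balance Modelling and Climate-Growth Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for dendroclimatic analysis of temperate forest
    stands: simulates daily forest water balance (soil moisture, relative
    extractable water, potential and actual transpiration) from standard
    meteorological series with slope/aspect radiation correction; models the
    phenological growing season (leaf unfolding and leaf coloring) of
    deciduous stands; detrends tree-ring width series with a species-specific
    age curve; aggregates daily output into standardized seasonal growth
    factors with one- and two-year lags; fits linear mixed-effects
    climate-growth sensitivity models with site random intercepts and
    backward AIC elimination; and projects ring-width residuals under
    looped-baseline and RCP-style delta-change climate scenarios. Includes a
    synthetic-data generator with known ground truth so the whole pipeline
    can be exercised and validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nlme,
    minpack.lm,
    lhs,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
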