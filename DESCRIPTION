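Package: hatchphen
Title: Thermal Development Models and Hatch Phenology for Atlantic Salmon
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modelling the thermal developmental phenology of
    Atlantic salmon (Salmo salar) embryos. Implements four published
    temperature-driven development models (Crisp, Gorodilov, WinSIRP and
    Kane) with daily rate-summation accumulation over arbitrary water
    temperature series, logistic estimation of the timing of 50% and 90%
    hatch from incubation-tube counts, repeatability statistics (one-way
    intraclass correlation and random-intercept mixed models), paired
    evaluation of observed versus model-predicted accumulated thermal
    units, and prediction of hatch and emergence windows in the wild from
    river temperature records and an assumed spawning period. A synthetic
    data module generates laboratory incubation regimes, seasonal river
    temperature series and split-brood hatch experiments with known
    generating parameters.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
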