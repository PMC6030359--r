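Package: nectartherm
Title: Thermal Response of Floral Nectar Secretion and Flower Production
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing temperature effects on floral nectar
    secretion in climate-chamber experiments. Derives per-plant nectar
    traits (volume, sugar concentration, sugar content per flower and per
    plant, flower number) from per-flower measurements, fits quadratic
    temperature-response linear mixed models with plant-level random
    intercepts, estimates thermal optima and 5-percent-band optimal
    temperature ranges from the fitted curves, models empty-flower excess
    with zero-inflated negative-binomial regression, and compares species
    group optima against baseline and projected end-of-century climates
    with paired t-tests. Includes a seeded synthetic-data generator that
    emulates the stepped-temperature chamber design so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
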