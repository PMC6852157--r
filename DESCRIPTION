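Package: bencounter
Title: Functional Responses and Biomass Encounter Rates for Benthic Consumers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising consumer-resource feeding interactions
    in the marine benthos. Fits generalised Holling functional responses to
    depletion-design feeding trials via the Rogers random-predator equation
    (solved with the Lambert-W function), selects among type I/II/III and
    general response shapes by small-sample AICc with a proportional-consumption
    diagnostic, derives capture rates at half-saturation and maximum feeding
    rates in biomass units, fits random-intercept mixed models over the full
    hierarchical set of metabolic fixed-effect structures, and simulates
    unitary and biomass resource encounter rates with an agent-based model of
    active and passive (filter-feeding) encounter strategies. A synthetic-data
    generator reproduces the statistical structure of trial-level and
    meta-level feeding data so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    lme4,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    pracma
Config/testthat/edition: 3
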