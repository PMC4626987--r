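Package: heatband
Title: Apparent-Temperature Heat-Day Projections from Bias-Corrected
    Climate Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to translate gridded daily climate-model ensembles into
    heat-health indicators. The pipeline bias-corrects daily maximum
    temperature (additive) and relative humidity (multiplicative) against a
    reference monthly climatology, computes the daily maximum apparent
    temperature from temperature, humidity and wind with the non-radiative
    Australian Bureau of Meteorology index, counts annual threshold-exceedance
    "hot days" and symptom-band days per grid cell, and characterises their
    trends with 11-year moving averages, ensemble percentile envelopes,
    average rates of increase, and a Monte Carlo re-randomization trend test.
    A seeded synthetic-climate generator with known ground truth (seasonal
    cycles, warming trends, systematic model biases, day-to-day noise) makes
    every stage testable without external model output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
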