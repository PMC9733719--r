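Package: pigflow
Title: Drinker-Use Analytics for Finisher Pig Pens
Version: 0.1.0
Authors@R:
    person("Pen", "Sensor Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pipeline for pen-level analysis of drinking-water sensor data from
    finisher pigs: calibration of pulse-count flow meters, aggregation of flow
    events to hourly water use and drinker activations per pig, residual-based
    outlier cleaning, square-root-scale harmonic (cosinor) mixed models of the
    diurnal pattern and age trend with AR(1) hourly correlation, time-period by
    week by treatment analyses, paired comparisons of the two drinking-cup
    locations, and matched case-control analysis of pens around tail-damage
    events. Includes a seeded synthetic-data generator that emulates the
    statistical structure of such studies with ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nlme,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
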