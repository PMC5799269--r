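Package: rootcap
Title: Soil-Water-Corrected Root Electrical Capacitance Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for normalizing root electrical capacitance (C_R)
    measurements for soil water status. Fits species-specific
    exponential calibration functions between relative root capacitance
    and relative soil water saturation from pot wetting-up series,
    inverts them to convert field (C_R, theta_rel) readings into the
    apparent saturation capacitance C_R* (a soil-moisture-independent
    root activity indicator), and provides the field statistics used in
    seasonal root monitoring: group poolability checks, per-day
    summaries, consecutive-day and treatment comparisons, and per-day
    capacitance-moisture regressions. A seeded synthetic-data generator
    emulates pot calibration series, field campaigns, soil capacitance
    surveys and destructive harvests so that the whole pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nlme,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
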