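Package: oncopolicy
Title: Discrete-Time Simulation of Cancer Healthcare Systems and Policy Scenarios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An age-structured, discrete-time (monthly) compartmental model of
    patient flow through a cancer healthcare system: incidence, staged
    progression while undiagnosed, detection, treatment at three quality
    tiers, recovery, death and spending. Includes multi-start calibration of
    detection/progression and recovery probabilities with practical
    identifiability diagnostics, time-dependent policy transitions and a
    prevention lever, Latin-hypercube uncertainty analysis with Monte-Carlo
    filtering, variance-based total-order sensitivity indices, and
    health-economic evaluation (NPV-based financing ratios, elasticities and
    internal rates of return). Seeded synthetic generators for demography,
    incidence and macroeconomic inputs allow the full pipeline to run
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lhs,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
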