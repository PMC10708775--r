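Package: crowdvitals
Title: Wearable-Vitals Consistency Monitoring and Safety Alerting in Simulated Crowds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates crowds of people wearing vital-sign sensors (SpO2, pulse,
    temperature, battery, 2-D position), windows the streams into sensing
    intervals, and scores each interval for saturation (sustained out-of-range
    drift) versus fluctuation (transient artifact) against a personal healthy
    baseline. A random-forest stage separates the two regimes; a correlation
    stage propagates consistency scores over interval series and decides
    normal/abnormal status; alerting covers threshold-distance violations
    between abnormal and nearby people, device-discharge estimation, and coded
    safety recommendations. Evaluation utilities compute false rate, spurious
    fluctuation rate, data-analysis rate, recommendation ratio and consistency
    check against simulator ground truth.
License: MIT
Encoding: UTF-8
Imports:
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
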