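Package: stepsense
Title: Open-Source Step Counting from Wrist-Worn Raw Accelerometry
Version: 0.1.0
Authors@R:
    person("Stepsense", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects steps in raw tri-axial wrist accelerometer recordings
    using an open peak-detection algorithm with magnitude, periodicity,
    similarity and continuity filters (two published parameter presets),
    aggregates step events into 5-second epochs with cadence and
    moderate-to-vigorous (MVPA, >= 100 steps/min) classification, builds
    daily and paired-day summaries, and quantifies concurrent validity
    against a reference device with Bland-Altman bias, limits of agreement,
    proportional bias, and mean absolute percent error. Includes an
    exhaustive parameter-grid tuner and a synthetic gait-signal simulator
    with ground-truth step logs so the whole pipeline is testable without
    device data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
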