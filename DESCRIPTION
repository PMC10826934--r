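Package: gpsactivity
Title: Quality Control and Validation of Smartphone GPS Activity-Space Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for cleaning and validating passively sensed smartphone
    GPS trajectories in activity-space research. Implements gap-based
    trajectory cleaning (study-window restriction, pooled 3-SD distance-jump
    removal, impossible-speed removal), participant- and point-level data
    quality metrics (time/distance gaps, accuracy, temporal coverage,
    participation days) with urban/non-urban and device stratification,
    buffered building-footprint home geofencing, concordance of GPS-derived
    at-home status against ecological momentary assessment (EMA)
    self-reports, and wake-time-at-home proportion estimation with group
    confidence intervals. Includes a synthetic cohort generator with ground
    truth labels so the full pipeline can be exercised and verified end to
    end without access to restricted study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
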