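Package: mocapqc
Title: Post Hoc Quality Control for Markerless Motion Capture Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post hoc quality control for depth-camera recordings of short
    structured motor tasks. Provides a plain-text recording container
    (16-bit PNG depth frames plus CSV skeleton time series), condensed
    motion-profile images, per-task characteristic signal extraction
    (positions, knee amplitudes, arm sway, step and sit-to-stand phase
    detection), automated detectors for a 12-criterion quality taxonomy,
    a two-rater usability-rating data model with concordance statistics,
    and a synthetic recording simulator with injectable ground-truth
    defects so the whole pipeline can be validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    zoo,
    withr,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
SystemRequirements: zlib
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
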