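Package: posturewatch
Title: Postural-Change Monitoring from Pose-Estimation Keypoint Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns per-second human-pose keypoint streams (17-keypoint
    PoseNet-style JSON) into bounding-box change features -- height,
    width and center-displacement deltas -- and classifies them as pose
    conversion, body movement or positional change for nonintrusive
    in-home care monitoring. Provides minute-level simple-moving-average
    summaries, daily cumulative totals and active-hours rollups,
    presence/absence segmentation, a predicted-versus-reference
    bounding-box agreement protocol with difference-value binning, a
    synthetic skeleton-motion simulator with ground-truth activity
    labels for end-to-end testing, pose-map and activity-chart
    rendering, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
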