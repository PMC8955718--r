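Package: speedkin
Title: Video-Based Kinematic Analysis of Speed Climbing Runs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Turns 2D pose keypoints (OpenPose BODY_25 dialect) and climbing-hold
    detections from monocular speed-climbing video into comparable kinematic
    parameters. Estimates per-frame vertical camera motion from feature-match
    pairs, calibrates a pixel-to-metric scale model against the standardized
    route map, computes segment-mass center-of-gravity trajectories and joint
    angles, detects hold contact intervals from filtered limb-speed curves, and
    summarises runs into section-wise parameter sets. Includes a synthetic-climb
    generator (climber trajectory, panning camera, perspective-free projection,
    keypoint noise and dropout, feature-match pairs) providing ground truth for
    every pipeline stage, plus a classical HSV hold segmenter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    minpack.lm,
    EBImage,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
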