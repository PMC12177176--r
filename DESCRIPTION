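Package: splitgaze
Title: Optical Morphometry and Gaze Kinematics of Split Compound Eyes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs per-ommatidium lens optics of miniature split
    compound eyes (as found in whiteflies) from digitized 3D landmarks:
    least-squares circle fits of the lens base, spherical-cap curvature
    radii, unit visual axes, interommatidial angles and per-section mean
    gaze. Simulates gaze direction under body yaw, pitch and roll on a
    virtual sphere, extracts flight and head kinematics from high-speed
    3D tracks, and ships a seeded synthetic-data generator producing
    ground-truth eyes and flight trajectories so that every analysis
    stage is testable without raw specimen data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
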