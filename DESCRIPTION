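Package: handmocap
Title: Multi-Camera Markerless Hand Motion Capture
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Processing chain for markerless hand motion capture from
    multiple calibrated video cameras. Triangulates 21-landmark hand
    keypoint tracks by direct linear transform, selects the optimal
    camera subset per trial from reprojection and anatomical
    (segment-length consistency) error criteria, fits a scaled
    articulated hand skeleton by weighted inverse kinematics, and
    computes occlusion-aware comparison metrics (joint-angle RMSE with a
    50 percent occlusion exclusion rule, range of motion, IK marker
    residuals) against a marker-based reference. Includes a synthetic
    articulated-motion simulator with virtual camera rigs for validation,
    zero-phase trajectory filtering, and readers/writers for C3D, TRC and
    CSV motion-capture formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
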