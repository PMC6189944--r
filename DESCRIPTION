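Package: servotrack
Title: High-Speed Visual-Servoing Tracking Simulator for Motile
    Microorganisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Closed-loop simulator of a high-speed microscopy platform that
    keeps a single motile microorganism centred in the field of view by
    visual servoing.  Implements moment-based target detection on binarized
    frames (centre of gravity and posture angle from image moments up to
    order two), frame-to-frame propagation of a rotated elliptical region
    of interest seeded by the previous frame's state, a
    magnification-dependent pixel-pitch model interpolated from a
    calibration table, a ground-truthed synthetic scene generator (beads,
    elongated swimmers, per-frame circular image noise, illumination drift,
    chip edges and an intruding microtool), a virtual XY stage with a
    saturated proportional servo law, the four-step search/track/zoom
    state machine, and evaluation harnesses reproducing search-time,
    velocity-sweep and noise-robustness experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    EBImage,
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
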