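Package: gazeqc
Title: Data-Quality Evaluation for Head-Mounted Eye-Trackers
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the data quality of wearable (head-mounted)
    eye-trackers from scene-camera recordings: localization of gaze targets
    in the scene video (circular Hough transform for dot grids and a
    bullseye, vanishing-point priors from carpet edges), gaze-signal
    preprocessing (missing-aware moving median, per-frame averaging),
    angular-error computation against a virtual-viewing-distance camera
    model, interval segmentation for seated and walking protocols, and
    accuracy, bias, precision, target-speed and heatmap metrics with the
    accompanying repeated-measures statistics. Includes a synthetic-session
    simulator with full ground truth for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
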