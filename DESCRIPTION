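Package: swaybalance
Title: Markerless Video-Based Postural Sway Assessment with Force-Plate Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies static standing balance from plain video by
    frame-difference motion segmentation, morphological denoising and
    silhouette-centroid tracking, and computes the standard stabilometric
    sway parameters (mean velocity, velocity variability and total path
    length in the mediolateral, anteroposterior and radial directions)
    identically for video-derived centre-of-mass trajectories and
    force-plate centre-of-pressure recordings.  Includes the force-plate
    conditioning chain (100 Hz sampling, fourth-order 10 Hz low-pass
    Butterworth filtering), a concurrent-validity statistics workflow
    (normality screening with log transformation, Mann-Whitney group
    comparisons, Pearson correlation with strength labels, predictor
    selection and Enter-method regression with Cohen effect-size bands),
    and a synthetic paired video/centre-of-pressure generator with known
    ground truth for end-to-end verification.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    signal,
    e1071,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
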