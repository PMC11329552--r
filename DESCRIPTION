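Package: rimest
Title: Surrogate-Based Estimation of Liver Respiratory-Induced Motion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates liver respiratory-induced motion from abdominal
    surface displacement used as a surrogate signal. Provides a scalar
    surrogate computed as the mean closest-point distance between each
    surface point cloud and a maximum-inhalation reference cloud,
    polynomial ordinary-least-squares correspondence models trained under
    single, session-specific and combined regimes, extraction of
    ground-truth liver displacement from binary segmentation mask
    sequences by edge tracking, segmentation quality metrics (Dice,
    Hausdorff, ROI-restricted Hausdorff), timestamp and breath-hold
    stream synchronization, and a simulator of a robotic breathing
    phantom and a multi-session clinical protocol so the full pipeline
    can be exercised end-to-end on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    signal,
    pracma,
    png,
    jsonlite,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
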