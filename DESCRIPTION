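Package: maqfacs
Title: Automatic Facial Action Unit Recognition for Macaque Face Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automatic recognition of macaque facial action units
    (MaqFACS) in head-fixed frontal face video. Implements landmark-based
    affine alignment of frames to a common face-centred coordinate system,
    region-of-interest cropping, delta-image construction against an optimal
    neutral frame, eigenface (snapshot PCA) feature extraction with
    explained-variance dimensionality selection, K-nearest-neighbour and
    linear support-vector classification of upper- and lower-face action
    units, class-balanced undersampling, within-subject, across-subject and
    stratified-holdout validation designs with grid-searched hyperparameters,
    and downstream behavioural (action-unit combination proportions,
    chi-square tests) and neural (peri-event z-scored firing rate) summaries.
    Ships a parametric synthetic face-video generator so the whole pipeline is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    png,
    stats,
    tiff,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
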