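Package: gazedx
Title: Dynamic Visual Attention Analysis for Autism Screening from Eye Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for eye-tracking-based behavioural phenotyping with split-screen
    preferential-looking video stimuli. Implements velocity-threshold (I-VT) fixation
    detection with merge/discard post-processing and angular geometry, per-frame group
    fixation heatmaps and difference-of-fixation (DoF) maps, a compact convolutional
    recurrent video saliency network trained on DoF targets with KL/correlation/NSS
    losses, fixation-indexed feature cascading with linear SVM classification under
    leave-one-out cross-validation, preferential-looking (Geo percentage) statistics
    with threshold and handcrafted-feature baselines, and a synthetic cohort generator
    so the full pipeline is testable end to end without any recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    randomForest,
    rpart,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
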