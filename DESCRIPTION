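Package: fetoseg
Title: Laser Ablation Detection and Workflow Segmentation for Fetoscopic Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frame-level detection of laser photocoagulation in fetoscopic
    video of twin-to-twin transfusion syndrome (TTTS) therapy, and
    segmentation of procedures into ablation / targeting / other workflow
    phases. Provides a synthetic fetoscopy-frame simulator with ground-truth
    labels, a compact convolutional binary ablation classifier with
    input-resolution and pooling variants, a channel-swap inference rule that
    derives the three-phase labelling from the binary detector alone, an
    SVM-on-colour-histogram baseline, and a leave-one-out evaluation
    protocol with precision/recall/F-measure reports, confusion tables,
    precision-recall curves and phase timelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    graphics,
    grDevices,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
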