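Package: laryngoscreen
Title: Segmentation-Based Screening of Laryngopharyngeal Cancer in
    Endoscopy Images and Videos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for computer-aided detection of
    laryngopharyngeal cancer in flexible laryngoscopy: a U-Net semantic
    segmentation network (native implementation with seeded training),
    morphological cleanup and connected-component area thresholding for
    frame-level cancer calls, a consecutive-duration rule for video-level
    diagnosis, and a diagnostic-evaluation toolbox (Clopper-Pearson and
    Wald binomial intervals, ROC/AUC, segmentation IoU, Cohen's kappa,
    exact and chi-square McNemar tests). Supports white-light (WLI) and
    narrow-band (NBI) imaging modalities, reads labelme-style polygon
    annotations and patient-level dataset manifests, and ships a
    seed-controlled synthetic endoscopy generator so every stage is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    e1071,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
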