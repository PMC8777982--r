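Package: dsvessel
Title: Dual-Stream Shallow Networks for Retinal Vessel Segmentation and
    Retinopathy Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements two shallow dual-stream encoder-decoder networks
    (DSF-Net, fusing streams by element-wise addition, and DSA-Net,
    aggregating them by depth-wise concatenation) for semantic segmentation
    of retinal blood vessels in colour fundus photographs, together with
    their training regime (Adam on a Generalized Dice Loss with global L2
    gradient normalization), pixel-level evaluation statistics (accuracy,
    sensitivity, specificity, ROC AUC, paired t-test model comparison),
    DRIVE-/STARE-/CHASE-DB1-style dataset catalogs with flip/translation
    augmentation and fixed, leave-one-out and two-fold split schemes, a
    deterministic synthetic fundus generator so the whole pipeline runs
    without external data, and the vessel-ratio screening statistic for
    longitudinal diabetic/hypertensive retinopathy flagging. All network
    arithmetic is implemented natively via 'RcppArmadillo'.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    tiff,
    jpeg,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
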