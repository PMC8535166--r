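Package: bleedrank
Title: Automatic Bleeding-Level Ranking for Endoscopic Surgery Videos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks intraoperative bleeding severity in transurethral resection
    of the prostate (TURP) surgery videos on a four-level ordinal scale.
    Frames are screened for blood in YCbCr color space, the red-glowing
    electrosurgical cutting loop is removed with a compact residual U-Net
    segmenter so its glare is not mistaken for blood, and per-video features
    (bleeding ratio and number of bleeding regions) are classified with
    k-nearest neighbors, Gaussian naive Bayes, random forest, or a support
    vector machine. Includes adjacent-level-tolerant ("revised") evaluation
    metrics, rank correlation against expert consensus scores, and a
    synthetic surgical-frame generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    png,
    randomForest,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
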