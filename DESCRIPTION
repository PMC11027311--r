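Package: mammogist
Title: Global Radiomic Features and the Radiologist Gist Signal in
    Screening Mammography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links computer-extracted global radiomic features (GRFs) of
    craniocaudal mammograms to the strength of radiologists' rapid "gist"
    impression. Implements the full analysis chain: breast-mask
    thresholding, laterality standardization and cropping, disk-erosion
    region-of-interest extraction, a 130-feature descriptor (110 gray-level
    co-occurrence matrix texture statistics at five pixel distances plus 20
    first-order intensity statistics), quartile labeling of averaged
    multi-observer gist scores, per-category bagged random-forest
    classification of high- versus low-gist images with minority
    oversampling and cross-validated AUC, and scree-test selection of the
    driving features. A synthetic-cohort generator emulates the study
    design so that every stage is testable without access to clinical
    images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    randomForest,
    stats,
    tools,
    tiff,
    png,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
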