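Package: ChoroidCVI
Title: Choroidal Vascularity Quantification and Cohort Analysis for OCT B-Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies the choroidal vasculature on swept-source OCT B-scans:
    Niblack auto-local thresholding of the segmented choroidal band into
    vascular lumen and extravascular stroma, choroidal thickness and
    luminal/stromal area metrics with Bennett axial-length magnification
    correction, and a fovea-centered regional grid. Includes eye-clustered
    cohort statistics (exchangeable-GEE group contrasts, standardized
    logistic and linear regression with cluster-robust errors, ROC/Youden
    diagnostic cut-offs with DeLong intervals) and a synthetic B-scan and
    cohort generator with exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tiff,
    png,
    jsonlite,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'ChoroidCVI-package.R'
    'binarization.R'
    'cohort-stats.R'
    'io.R'
    'pipeline.R'
    'regional-metrics.R'
    'roc.R'
    'scale-correction.R'
    'segmentation.R'
    'synthetic-cohort.R'
    'synthetic-oct.R'
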