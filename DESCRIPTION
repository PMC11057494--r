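Package: echolvef
Title: Automated Left-Ventricular Ejection-Fraction Estimation from
    Apical-4-Chamber Echocardiograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An automated pipeline for estimating left-ventricular ejection
    fraction (LVEF) from apical-4-chamber echocardiographic cine loops.
    Segments the left ventricle with an atrous convolutional network,
    extracts a per-frame area curve, detects every end-diastolic and
    end-systolic frame by prominence-based peak detection, refines the
    per-cycle areas with a percentile-pooled (improved Jeffrey's) method,
    predicts LV length with a voting ensemble regressor, converts areas and
    lengths to volumes with the single-plane area-length (ellipsoid) model,
    averages ejection fraction over all cardiac cycles and classifies the
    heart-failure phenotype. A synthetic pulsating-ellipse simulator with
    analytic ground truth makes every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tiff,
    jsonlite,
    Rcpp,
    ranger,
    rpart,
    glmnet,
    xgboost,
    caret,
    pROC,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
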