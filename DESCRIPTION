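Package: broilerwt
Title: Broiler Body-Weight Estimation from Top-View Depth Images
Version: 0.1.0
Authors@R: 
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Estimates the body weight of broiler chickens from top-view
    depth images. Provides a synthetic depth-scene simulator with analytic
    ground truth (half-ellipsoid domes on a flat ground plane), 16-bit
    depth PNG input/output with JET pseudo-colour rendering, depth-threshold
    instance segmentation with a pluggable external-segmenter contract,
    extraction of 25 morphometric features from instance masks and depth
    values (contour, convex hull, convexity defects, fitted ellipse, depth
    statistics, approximate dome volume), fusion with a 2048-dimensional
    learned-feature embedding contract, a from-scratch gradient-boosted
    regression-tree weight estimator, and evaluation utilities (MAE, MSE,
    RMSE, R-squared, weight-class error breakdown, grouped train/test
    splits, end-to-end parameter-recovery experiments).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
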