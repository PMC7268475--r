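Package: uasyield
Title: UAS Multi-Sensor Feature Extraction and Yield Prediction for Soybean Breeding Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested pipeline for predicting soybean grain yield from
    unmanned-aircraft-system (UAS) imagery of breeding trials. Extracts
    per-plot radiometric features from four-band (green, red, red-edge,
    near-infrared) orthomosaics using k-means end-member segmentation and
    Gaussian plus robust statistics (median, NMAD, biweight midvariance,
    interpercentile ranges) together with a panel of vegetation indices;
    extracts per-plot geometric features (canopy height and mesh canopy
    volume) from photogrammetric point clouds by statistical outlier
    filtering, iterative-closest-point registration, local quadric terrain
    differencing, fixed-bar height calibration and Delaunay-based volume
    integration; fits bagged-forest and boosted-tree yield regressions; and
    evaluates them with bias/error metrics, a bisquare robust linear fit
    with studentized-residual outlier flagging, a robust Jarque-Bera
    normality test and family-grouped errors. A synthetic-field generator
    emulating the flight and harvest data drives the test suite end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    RANN,
    interp,
    jsonlite,
    ranger,
    tiff,
    xgboost,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    knitr
Config/testthat/edition: 3
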