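Package: graincloud
Title: 3D Point-Cloud Phenotyping and Classification of Filled and Unfilled Grains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for structured-light 3D seed phenotyping: synthetic
    scanner-scene generation, single-grain segmentation (PCA frame transform,
    RANSAC plate removal, region growing), moving-least-squares point-cloud
    enhancement (normal estimation and up-sampling), extraction of eleven 3D
    shape traits (oriented-bounding-box dimensions, mesh surface and volume,
    per-axis projected area and perimeter), a six-model machine-learning
    baseline with cross-validation, and a hierarchical point-set (improved
    PointNet++-style) classifier for filled versus unfilled grain point clouds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    rpart,
    randomForest,
    e1071,
    nnet,
    xgboost
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
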