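Package: uavpheno
Title: Individual-Plant Phenotyping and Weight Prediction from Multi-Temporal UAV Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for individual-plant phenotyping from multi-temporal UAV
    orthomosaic imagery. Consolidates per-flight plant detections into one
    georeferenced bounding box per plant and indexes boxes to a sowing grid;
    builds plant-height rasters from point clouds; co-registers multispectral
    to RGB geometry by phase cross-correlation; cuts per-plant 4-D image
    stacks; computes vegetation indices with correlation pruning and a
    three-stage noise-filter cascade (k-means soil mask, contour area filter,
    RGB histogram equalization); summarizes stacks into per-time-point
    features (layer medians, 90th-percentile plant height, leaf angle,
    canopy volume); and runs multi-temporal harvest-weight regression
    experiments (feature selection, five regressor families under five-fold
    cross-validation, temporal-resolution and days-prior-to-harvest sweeps).
    A fully specified synthetic-field generator with known ground truth
    exercises the whole pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tiff,
    jsonlite,
    yaml,
    glmnet,
    e1071,
    randomForest,
    mixOmics,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
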