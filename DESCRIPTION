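Package: polarSlice
Title: Band-Slicing Features and Ensemble Classification of Myocardial
    Perfusion Polar Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to distinguish normal from abnormal myocardial-perfusion
    SPECT polar maps (bull's-eye plots). Implements intensity band-slicing
    feature extraction (summed pixel intensities over five horizontal and
    five vertical image bands), rotation-based augmentation of the minority
    normal class restricted to training partitions, stratified leakage-free
    k-fold cross-validation, four ensemble classifier families (adaptive
    boosting, gradient boosting, random forest, extreme gradient boosting),
    and fold-wise accuracy/precision/sensitivity/F1/AUC reporting with
    mean and standard-deviation aggregation. Includes a synthetic polar-map
    generator that emulates the circular uptake disc, angular-sector
    perfusion defects, and the class/phase/sex structure of a clinical
    polar-map archive, so the whole pipeline is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tiff,
    randomForest,
    xgboost,
    rpart,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'PolarMapSet-class.R'
    'augment.R'
    'cli.R'
    'metrics.R'
    'crossval.R'
    'features.R'
    'io.R'
    'models.R'
    'polarSlice-package.R'
    'synth.R'
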