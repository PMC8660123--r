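rfOnly <- function(seed = 1L, ntree = 100L)
    list(modelSpec("random_forest", seed = seed,
                   params = list(ntree = ntree)))

test_that("stratified folds balance both class and total counts", {
    labels <- rep(c(1, 0), c(10, 10))
    f <- makeFolds(labels, k = 10, seed = 3)
    expect_true(all(table(f) == 2))
    expect_true(all(table(f, labels) == 1))   # one per class per fold

    big <- rep(c(0, 1), c(899, 108))
    f10 <- makeFolds(big, k = 10, seed = 7)
    expect_true(all(table(f10) %in% c(100L, 101L)))
    perFoldNormals <- table(f10[big == 1])
    expect_lte(max(perFoldNormals) - min(perFoldNormals), 1L)
    expect_identical(f10, makeFolds(big, k = 10, seed = 7))
    expect_false(identical(f10, makeFolds(big, k = 10, seed = 8)))
})

test_that("fold-count edge cases error or warn as documented", {
    expect_error(makeFolds(c(0, 1, 0), k = 5), "exceeds")
    expect_error(makeFolds(rep(0, 10), k = 1), "at least 2")
    expect_warning(makeFolds(rep(c(0, 1), c(20, 2)), k = 5),
                   "fewer than k")
})

test_that("a fold partitions the data and never leaks augmented sources", {
    pms <- simulatePolarMaps(8, 16, tinyConfig(), seed = 41)
    folds <- makeFolds(mapLabels(pms), k = 4, seed = 2)
    cfgNoAug <- pipelineConfig(k = 4, models = rfOnly(),
                               augmentation = NULL)
    res <- runFold(pms, folds, 1L, rfOnly()[[1L]], cfgNoAug)
    expect_equal(res$audit$nTrain + res$audit$nTest, length(pms))
    expect_equal(res$audit$nAugmented, 0L)

    cfgAug <- pipelineConfig(k = 4, models = rfOnly())
    res2 <- runFold(pms, folds, 2L, rfOnly()[[1L]], cfgAug)
    nTrainNormals <- sum(mapLabels(pms)[folds != 2L] == 1L)
    expect_equal(res2$audit$nAugmented, 3L * nTrainNormals)
    expect_equal(res2$audit$nLeaked, 0L)
    expect_setequal(res2$metrics$partition,
                    c("train", "train_unaugmented", "test"))
})

test_that("training on a single-class partition is refused", {
    pms <- simulatePolarMaps(2, 10, tinyConfig(), seed = 42)
    folds <- c(1L, 1L, rep(2L, 5L), rep(3L, 5L))  # fold 1 holds all normals
    expect_error(runFold(pms, folds, 1L, rfOnly()[[1L]],
                         pipelineConfig(k = 3, models = rfOnly())),
                 "one class")
})

test_that("augmentation shifts the training class balance as expected", {
    # 10 normals / 30 abnormals, 3 copies each: normal training-row share
    # rises from 25% to 40/(30+40) = 4/7
    pms <- simulatePolarMaps(10, 30, tinyConfig(), seed = 43)
    folds <- makeFolds(mapLabels(pms), k = 5, seed = 1)
    res <- runFold(pms, folds, 1L, rfOnly()[[1L]],
                   pipelineConfig(k = 5, models = rfOnly()))
    nN <- sum(mapLabels(pms)[folds != 1L] == 1L)
    nA <- sum(mapLabels(pms)[folds != 1L] == 0L)
    trainRows <- res$metrics$nTrain[1L] + res$metrics$nAugmented[1L]
    expect_equal(trainRows, nN * 4L + nA)
    expect_equal(4 * nN / (4 * nN + nA), 4 * 8 / (4 * 8 + 24))
})

test_that("a full run covers every acquired map exactly once in test", {
    pms <- simulatePolarMaps(10, 25, tinyConfig(), seed = 44)
    cfg <- pipelineConfig(k = 5, seed = 6, models = rfOnly())
    rep1 <- runCV(pms, cfg)
    folds <- rep1@folds
    expect_setequal(names(folds), mapData(pms)$mapId)
    fm <- foldMetrics(rep1)
    expect_equal(nrow(fm[fm$partition == "test", ]), 5L)
    expect_equal(sum(fm$nTest[fm$partition == "test"]), length(pms))
    expect_true(all(leakageAudit(rep1)$nLeaked == 0L))
    # end-to-end determinism (wall time is the only column allowed to vary)
    rep2 <- runCV(pms, cfg)
    noTime <- function(df) df[, setdiff(names(df), "elapsedSeconds")]
    expect_identical(noTime(foldMetrics(rep1)), noTime(foldMetrics(rep2)))
})

test_that("augmented maps never enter a fold plan", {
    pms <- simulatePolarMaps(6, 12, tinyConfig(), seed = 45)
    aug <- augmentNormals(pms, augmentationConfig())
    mixed <- c(pms, aug)
    rep <- runCV(mixed, pipelineConfig(k = 3, models = rfOnly()))
    expect_setequal(names(rep@folds), mapData(pms)$mapId)
    expect_false(any(mapData(aug)$mapId %in% names(rep@folds)))
})

test_that("feature-matrix cross-validation requires augmentation off", {
    fm <- buildFeatureMatrix(simulatePolarMaps(8, 16, tinyConfig(),
                                               seed = 46))
    expect_error(runCV(fm, pipelineConfig(k = 4, models = rfOnly())),
                 "augmentation")
    rep <- runCV(fm, pipelineConfig(k = 4, models = rfOnly(),
                                    augmentation = NULL))
    fmet <- foldMetrics(rep)
    expect_equal(nrow(fmet[fmet$partition == "test", ]), 4L)
    expect_true(all(fmet$nAugmented == 0L))
})

test_that("severe noise-free defects are separated by every family", {
    pms <- simulatePolarMaps(15, 30,
                             noiseFreeConfig(imageSize = 35L,
                                             defectSeverityRange = c(0.9, 1)),
                             seed = 47)
    cfg <- pipelineConfig(k = 3, seed = 2, models = smallModelSpecs())
    rep <- runCV(pms, cfg)
    s <- cvSummary(rep)
    aucs <- s[s$partition == "test" & s$metric == "auc", ]
    expect_equal(nrow(aucs), 4L)
    expect_true(all(aucs$mean > 0.9))
})

test_that("the summary aggregates exactly the per-fold values it reports", {
    pms <- simulatePolarMaps(8, 16, tinyConfig(), seed = 48)
    rep <- runCV(pms, pipelineConfig(k = 4, seed = 3, models = rfOnly()))
    fm <- foldMetrics(rep)
    s <- cvSummary(rep)
    testAcc <- fm$accuracy[fm$partition == "test"]
    row <- s[s$partition == "test" & s$metric == "accuracy", ]
    expect_equal(row$mean, mean(testAcc))
    expect_equal(row$sd, stats::sd(testAcc))
})
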