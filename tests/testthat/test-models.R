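# a tiny linearly separable feature matrix: class 0 has uniformly larger
# band sums than class 1, duplicated with jitter-free copies
toyMatrix <- function(nPerClass = 2L) {
    lo <- matrix(rep(c(10, 20, 30, 40, 50, 30, 30, 30, 30, 30),
                     each = nPerClass), nPerClass, 10)
    hi <- lo + 500
    out <- rbind(cbind(hi, 0), cbind(lo, 1))
    colnames(out) <- c(paste0("h", 1:5), paste0("v", 1:5), "label")
    out
}

separableSet <- function(nN = 10L, nA = 20L, seed = 21L)
    simulatePolarMaps(nN, nA,
                      noiseFreeConfig(imageSize = 35L,
                                      defectSeverityRange = c(0.9, 1)),
                      seed = seed)

test_that("random forest saturates training accuracy on separable toys", {
    fm <- toyMatrix()
    model <- trainModel(modelSpec("random_forest"), fm)
    expect_equal(predictLabels(model, fm), unname(fm[, "label"]))
    m <- computeMetrics(fm[, "label"], predictScores(model, fm))
    expect_equal(m[["accuracy"]], 1)
})

test_that("training is deterministic given the spec seed", {
    fm <- buildFeatureMatrix(separableSet())
    probe <- fm[sample(nrow(fm), 8L), , drop = FALSE]
    for (spec in smallModelSpecs(seed = 5L)) {
        m1 <- trainModel(spec, fm)
        m2 <- trainModel(spec, fm)
        expect_identical(predictScores(m1, probe),
                         predictScores(m2, probe))
    }
})

test_that("scores are probabilities and duplicates score identically", {
    fm <- buildFeatureMatrix(separableSet())
    dup <- rbind(fm[3L, 1:10, drop = FALSE], fm[3L, 1:10, drop = FALSE])
    for (spec in smallModelSpecs()) {
        model <- trainModel(spec, fm)
        s <- predictScores(model, fm)
        expect_true(all(s >= 0 & s <= 1))
        sd2 <- predictScores(model, dup)
        expect_identical(sd2[1L], sd2[2L])
    }
})

test_that("hard labels follow the documented >= threshold tie rule", {
    fm <- buildFeatureMatrix(separableSet())
    model <- trainModel(modelSpec("random_forest",
                                  params = list(ntree = 100L)), fm)
    s <- predictScores(model, fm)
    # at threshold exactly equal to a row's score, that row is positive
    for (i in c(1L, nrow(fm)))
        expect_equal(predictLabels(model, fm, threshold = s[i])[i],
                     model$positiveClass)
    # monotone: raising the threshold never adds positives
    sweep <- sort(unique(c(0, s, 1)))
    nPos <- vapply(sweep, function(th)
        sum(predictLabels(model, fm, threshold = th) == 0L), numeric(1))
    expect_true(all(diff(nPos) <= 0))
    # all-zero scores at threshold 0.5 predict everything negative
    expect_true(all(ifelse(rep(0, 4) >= 0.5, 0L, 1L) == 1L))
})

test_that("swapping the positive class flips scores consistently", {
    fm <- buildFeatureMatrix(separableSet())
    for (spec in smallModelSpecs(seed = 9L)) {
        mAbn <- trainModel(spec, fm, positiveClass = 0L)
        mNorm <- trainModel(spec, fm, positiveClass = 1L)
        sAbn <- predictScores(mAbn, fm)
        sNorm <- predictScores(mNorm, fm)
        # away from the 0.5 tie boundary the hard predictions must agree
        keep <- abs(sAbn - 0.5) > 1e-6 & abs(sNorm - 0.5) > 1e-6
        expect_gt(mean(keep), 0.5)
        expect_equal(predictLabels(mAbn, fm)[keep],
                     predictLabels(mNorm, fm)[keep])
    }
})

test_that("every family separates clean defects far better than chance", {
    train <- buildFeatureMatrix(separableSet(12L, 24L, seed = 31L))
    test <- buildFeatureMatrix(separableSet(8L, 16L, seed = 32L))
    for (spec in smallModelSpecs()) {
        model <- trainModel(spec, train)
        auc <- aucRank(predictScores(model, test), test[, "label"] == 0)
        expect_gt(auc, 0.9)
    }
})

test_that("degenerate inputs and bad hyperparameters are rejected", {
    fm <- toyMatrix()
    expect_error(modelSpec("random_forest", params = list(bogus = 1)),
                 "unknown hyperparameter")
    expect_error(modelSpec("neural_net"))
    oneClass <- fm[fm[, "label"] == 0, , drop = FALSE]
    expect_error(trainModel(modelSpec("random_forest"), oneClass),
                 "one class")
    expect_error(trainModel(modelSpec("random_forest"),
                            fm[1L, , drop = FALSE]), "2 training rows")
    model <- trainModel(modelSpec("random_forest"), fm)
    expect_error(predictScores(model, fm[, 1:4]), "10 columns|h1")
    expect_error(trainModel(list(), fm), "modelSpec")
})
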