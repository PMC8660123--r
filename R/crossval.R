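#' @include PolarMapSet-class.R metrics.R
NULL

#' Cross-validation pipeline configuration
#'
#' @param k number of folds (default 10).
#' @param seed integer seed for fold assignment (model seeds live in the
#'   individual [modelSpec()]s).
#' @param models list of [modelSpec()] objects to evaluate.
#' @param augmentation an [augmentationConfig()] applied to the normal maps
#'   of each fold's *training* partition, or `NULL` to disable augmentation.
#' @param positiveClass label value treated as positive for
#'   precision/sensitivity/AUC; default 0 (abnormal).
#' @param threshold decision threshold on positive-class scores.
#' @param sdType standard-deviation convention for aggregation
#'   (see [aggregateMetrics()]).
#' @return a list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(k = 10L, seed = 1L,
                           models = list(modelSpec("random_forest")),
                           augmentation = augmentationConfig(),
                           positiveClass = 0L, threshold = 0.5,
                           sdType = "sample") {
    k <- as.integer(k)
    if (k < 2L)
        stop("k must be at least 2")
    if (!is.list(models) || length(models) == 0L ||
        !all(vapply(models, inherits, logical(1), "ModelSpec")))
        stop("models must be a non-empty list of modelSpec() objects")
    if (!is.null(augmentation) &&
        !inherits(augmentation, "AugmentationConfig"))
        stop("augmentation must be NULL or an augmentationConfig()")
    if (!positiveClass %in% c(0L, 1L))
        stop("positiveClass must be 0 or 1")
    structure(list(k = k, seed = as.integer(seed), models = models,
                   augmentation = augmentation,
                   positiveClass = as.integer(positiveClass),
                   threshold = threshold, sdType = sdType),
              class = "PipelineConfig")
}

#' Stratified fold assignment
#'
#' Assigns samples to `k` folds so that (a) each class is spread as evenly
#' as possible across folds — every fold's class count is within one of any
#' other fold's — and (b) total fold sizes differ by at most one. Remainder
#' samples of each class are dealt to the folds with the smallest running
#' totals, which is what keeps both guarantees simultaneously. Deterministic
#' given `(labels, k, seed)`.
#'
#' @param labels vector of class labels (any atomic type).
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold indices in `1..k`, one per sample.
#' @examples
#' f <- makeFolds(rep(c(0, 1), c(899, 108)), k = 10, seed = 1)
#' table(f)  # all fold sizes 100 or 101
#' @export
makeFolds <- function(labels, k = 10L, seed = 1L) {
    n <- length(labels)
    k <- as.integer(k)
    if (k < 2L)
        stop("k must be at least 2")
    if (k > n)
        stop("k (", k, ") exceeds the number of samples (", n, ")")
    counts <- table(labels)
    if (any(counts < k))
        warning("some class has fewer than k samples; ",
                "folds will not all contain every class")
    set.seed(seed)
    fold <- integer(n)
    totals <- integer(k)
    for (cl in names(sort(counts, decreasing = TRUE))) {
        idx <- which(as.character(labels) == cl)
        idx <- idx[sample.int(length(idx))]
        m <- length(idx)
        perFold <- rep(m %/% k, k)
        rem <- m %% k
        if (rem > 0L) {
            recipients <- order(totals, stats::runif(k))[seq_len(rem)]
            perFold[recipients] <- perFold[recipients] + 1L
        }
        fold[idx] <- rep(seq_len(k), times = perFold)
        totals <- totals + perFold
    }
    fold
}

#' Cross-validation report
#'
#' Returned by [runCV()]. Holds the per-fold metric table, its mean +/- sd
#' aggregation, the fold assignment, the per-fold leakage audit, and a
#' snapshot of the effective configuration (including every model's
#' effective hyperparameters).
#'
#' @slot foldMetrics `data.frame`: one row per model x fold x partition with
#'   the five metrics, `elapsedSeconds` and partition sizes. Partitions are
#'   `test` (held-out acquired maps), `train` (the augmented training matrix
#'   the model was fitted on) and `train_unaugmented` (the same model scored
#'   on the acquired training rows only).
#' @slot summary aggregated table from [aggregateMetrics()].
#' @slot folds named integer vector: fold index per acquired map.
#' @slot leakageAudit `data.frame` per fold: training/test/augmented counts
#'   and the number of augmented training maps whose source map sits in that
#'   fold's test partition (must be 0 everywhere).
#' @slot config list snapshot of the effective configuration.
#' @export
setClass("CVReport",
         representation(foldMetrics = "data.frame", summary = "data.frame",
                        folds = "integer", leakageAudit = "data.frame",
                        config = "list"))

#' @rdname CVReport-accessors
#' @export
setGeneric("foldMetrics", function(x) standardGeneric("foldMetrics"))

#' @rdname CVReport-accessors
#' @export
setGeneric("cvSummary", function(x) standardGeneric("cvSummary"))

#' @rdname CVReport-accessors
#' @export
setGeneric("leakageAudit", function(x) standardGeneric("leakageAudit"))

#' @rdname CVReport-accessors
#' @export
setGeneric("cvConfig", function(x) standardGeneric("cvConfig"))

#' Accessors for CVReport
#'
#' `foldMetrics()` returns the per-fold metric table, `cvSummary()` the
#' aggregated mean +/- sd table, `leakageAudit()` the per-fold leakage audit,
#' and `cvConfig()` the effective configuration snapshot.
#'
#' @param x a [CVReport-class]
#' @return see description
#' @name CVReport-accessors
#' @export
setMethod("foldMetrics", "CVReport", function(x) x@foldMetrics)

#' @rdname CVReport-accessors
#' @export
setMethod("cvSummary", "CVReport", function(x) x@summary)

#' @rdname CVReport-accessors
#' @export
setMethod("leakageAudit", "CVReport", function(x) x@leakageAudit)

#' @rdname CVReport-accessors
#' @export
setMethod("cvConfig", "CVReport", function(x) x@config)

setMethod("show", "CVReport", function(object) {
    k <- length(unique(object@foldMetrics$fold))
    cat("CVReport:", k, "folds,",
        length(unique(object@foldMetrics$model)), "model(s)\n")
    leaks <- sum(object@leakageAudit$nLeaked)
    cat("  leakage audit:", if (leaks == 0L) "clean" else
        paste(leaks, "LEAKED AUGMENTED MAPS"), "\n\n")
    cat("Test partition (mean +/- sd):\n")
    print(formatReportTable(object, partition = "test"))
    invisible(object)
})

#' Render a CVReport block as a mean +/- sd table
#'
#' One row per model, one column per metric (plus mean wall time), each cell
#' formatted `"mean +/- sd"` — the conventional presentation of fold-wise
#' cross-validation results.
#'
#' @param report a [CVReport-class].
#' @param partition `"test"`, `"train"` or `"train_unaugmented"`.
#' @param digits decimal places.
#' @return a character `data.frame`, models as rows.
#' @export
formatReportTable <- function(report, partition = "test", digits = 3L) {
    s <- report@summary
    s <- s[s$partition == partition, , drop = FALSE]
    if (nrow(s) == 0L)
        stop("no rows for partition '", partition, "'")
    cols <- c("accuracy", "f1", "precision", "sensitivity",
              "elapsedSeconds", "auc")
    cols <- intersect(cols, unique(s$metric))
    models <- unique(s$model)
    out <- data.frame(row.names = models)
    for (m in cols) {
        sm <- s[s$metric == m, ]
        out[[m]] <- sprintf("%.*f +/- %.*f", digits,
                            sm$mean[match(models, sm$model)], digits,
                            sm$sd[match(models, sm$model)])
    }
    out
}

.timedMetrics <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- expr
    list(value = value, elapsed = proc.time()[["elapsed"]] - t0)
}

#' Run a single cross-validation fold
#'
#' The per-fold pipeline: the training partition is every acquired map not
#' assigned to `fold`; its normal maps are augmented with rotated copies;
#' features are extracted from the combined (acquired + augmented) training
#' maps; the model is trained on them; and the held-out fold's acquired maps
#' — never any augmented map — form the test partition. Because augmentation
#' happens after the split, no rotated copy of a test image can reach the
#' training set; the function asserts this and reports it in the audit row.
#'
#' @param x a [PolarMapSet-class] of acquired maps.
#' @param folds integer fold assignment from [makeFolds()] (one entry per
#'   map of `x`).
#' @param fold fold index to hold out.
#' @param spec a [modelSpec()].
#' @param config a [pipelineConfig()].
#' @return list with `metrics` (data.frame rows for partitions
#'   `train`, `train_unaugmented`, `test`) and `audit` (one-row data.frame).
#' @export
runFold <- function(x, folds, fold, spec, config = pipelineConfig()) {
    if (length(folds) != length(x))
        stop("folds must have one entry per map")
    if (!fold %in% folds)
        stop("fold ", fold, " has no test samples")
    trainSet <- x[folds != fold]
    testSet <- x[folds == fold]
    if (length(unique(mapLabels(trainSet))) < 2L)
        stop("degenerate training partition: only one class present")
    aug <- if (is.null(config$augmentation)) trainSet[integer(0)] else
        augmentNormals(trainSet, config$augmentation)
    nLeaked <- length(intersect(mapData(aug)$sourceMapId,
                                mapData(testSet)$mapId))
    stopifnot(nLeaked == 0L)   # by construction: augmentation after split
    trainAll <- if (length(aug) > 0L) c(trainSet, aug) else trainSet
    trainMat <- buildFeatureMatrix(trainAll)
    testMat <- buildFeatureMatrix(testSet)
    fitTimed <- .timedMetrics(trainModel(spec, trainMat,
                                         config$positiveClass))
    model <- fitTimed$value
    evalPartition <- function(mat, partition, elapsed) {
        met <- computeMetrics(mat[, "label"],
                              predictScores(model, mat),
                              threshold = config$threshold,
                              positiveClass = config$positiveClass)
        data.frame(model = spec$family, fold = fold, partition = partition,
                   t(met), elapsedSeconds = elapsed,
                   nTrain = length(trainSet), nTest = length(testSet),
                   nAugmented = length(aug))
    }
    trainAcqMat <- buildFeatureMatrix(trainSet)
    metrics <- rbind(
        evalPartition(trainMat, "train", fitTimed$elapsed),
        evalPartition(trainAcqMat, "train_unaugmented", fitTimed$elapsed),
        evalPartition(testMat, "test", fitTimed$elapsed))
    audit <- data.frame(fold = fold, nTrain = length(trainSet),
                        nTest = length(testSet), nAugmented = length(aug),
                        nLeaked = nLeaked)
    list(metrics = metrics, audit = audit)
}

#' Run the full cross-validation pipeline
#'
#' @description
#' Stratified k-fold cross-validation with training-fold-only augmentation.
#' Only `provenance = "acquired"` maps are ever assigned to folds or used as
#' test data; every acquired map appears in exactly one test partition across
#' the run. For each fold and each model, [runFold()] augments the training
#' normals, re-extracts features, trains, and evaluates on the held-out
#' acquired maps. Results are aggregated to mean +/- sd per model, partition
#' and metric.
#'
#' The matrix method runs the same fold/metric machinery on a precomputed
#' 11-column feature matrix; augmentation must be disabled
#' (`augmentation = NULL`) because rotated copies cannot be derived from
#' feature rows.
#'
#' @param x a [PolarMapSet-class], or an 11-column feature matrix
#'   (`h1..h5, v1..v5, label`).
#' @param config a [pipelineConfig()].
#' @param ... unused.
#' @return a [CVReport-class].
#' @examples
#' pms <- simulatePolarMaps(12, 28, polarMapConfig(imageSize = 35), seed = 1)
#' cfg <- pipelineConfig(k = 4, models = list(modelSpec("random_forest",
#'                                            params = list(ntree = 50))))
#' runCV(pms, cfg)
#' @export
setGeneric("runCV", function(x, config = pipelineConfig(), ...)
    standardGeneric("runCV"))

#' @rdname runCV
#' @export
setMethod("runCV", "PolarMapSet", function(x, config = pipelineConfig(),
                                           ...) {
    acq <- x[mapData(x)$provenance == "acquired"]
    if (length(acq) < config$k)
        stop("fewer acquired maps than folds")
    folds <- makeFolds(mapLabels(acq), k = config$k, seed = config$seed)
    names(folds) <- mapData(acq)$mapId
    metricRows <- list(); auditRows <- list()
    for (spec in config$models) {
        for (f in seq_len(config$k)) {
            res <- runFold(acq, folds, f, spec, config)
            metricRows[[length(metricRows) + 1L]] <- res$metrics
            if (spec$family == config$models[[1L]]$family)
                auditRows[[length(auditRows) + 1L]] <- res$audit
        }
    }
    .assembleReport(metricRows, auditRows, folds, config)
})

#' @rdname runCV
#' @export
setMethod("runCV", "matrix", function(x, config = pipelineConfig(), ...) {
    if (!is.null(config$augmentation))
        stop("augmentation requires images; pass augmentation = NULL ",
             "when cross-validating a precomputed feature matrix")
    x <- .checkFeatureColumns(x, requireLabel = TRUE)
    folds <- makeFolds(x[, "label"], k = config$k, seed = config$seed)
    metricRows <- list(); auditRows <- list()
    for (spec in config$models) {
        for (f in seq_len(config$k)) {
            trainMat <- x[folds != f, , drop = FALSE]
            testMat <- x[folds == f, , drop = FALSE]
            fitTimed <- .timedMetrics(trainModel(spec, trainMat,
                                                 config$positiveClass))
            model <- fitTimed$value
            rows <- lapply(list(train = trainMat, test = testMat),
                           function(mat)
                computeMetrics(mat[, "label"], predictScores(model, mat),
                               threshold = config$threshold,
                               positiveClass = config$positiveClass))
            metricRows[[length(metricRows) + 1L]] <- data.frame(
                model = spec$family, fold = f,
                partition = c("train", "test"),
                rbind(rows$train, rows$test),
                elapsedSeconds = fitTimed$elapsed,
                nTrain = nrow(trainMat), nTest = nrow(testMat),
                nAugmented = 0L)
            if (spec$family == config$models[[1L]]$family)
                auditRows[[length(auditRows) + 1L]] <- data.frame(
                    fold = f, nTrain = nrow(trainMat),
                    nTest = nrow(testMat), nAugmented = 0L, nLeaked = 0L)
        }
    }
    .assembleReport(metricRows, auditRows, folds, config)
})

.assembleReport <- function(metricRows, auditRows, folds, config) {
    perFold <- do.call(rbind, metricRows)
    rownames(perFold) <- NULL
    audit <- do.call(rbind, auditRows)
    rownames(audit) <- NULL
    snapshot <- list(
        k = config$k, seed = config$seed,
        positiveClass = config$positiveClass, threshold = config$threshold,
        sdType = config$sdType,
        augmentation = if (is.null(config$augmentation)) NULL else
            unclass(config$augmentation),
        models = lapply(config$models, unclass))
    methods::new("CVReport",
                 foldMetrics = perFold,
                 summary = aggregateMetrics(perFold, config$sdType),
                 folds = folds,
                 leakageAudit = audit,
                 config = snapshot)
}
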