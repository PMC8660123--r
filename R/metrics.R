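#' Confusion-matrix counts
#'
#' @param yTrue,yPred equal-length vectors of 0/1 labels.
#' @param positiveClass label value counted as positive (default 0,
#'   abnormal).
#' @return named integer vector `c(TP, FP, FN, TN)`; the four counts always
#'   sum to `length(yTrue)`.
#' @examples
#' confusionCounts(c(1,1,1,1,0,0,0,0,0,0), c(1,1,1,0,1,0,0,0,0,0),
#'                 positiveClass = 1)  # TP 3, FP 1, FN 1, TN 5
#' @export
confusionCounts <- function(yTrue, yPred, positiveClass = 0L) {
    if (length(yTrue) != length(yPred))
        stop("yTrue and yPred must have equal length")
    if (length(yTrue) == 0L)
        stop("need at least one observation")
    tp <- sum(yTrue == positiveClass & yPred == positiveClass)
    fp <- sum(yTrue != positiveClass & yPred == positiveClass)
    fn <- sum(yTrue == positiveClass & yPred != positiveClass)
    tn <- sum(yTrue != positiveClass & yPred != positiveClass)
    c(TP = tp, FP = fp, FN = fn, TN = tn)
}

#' Rank-based AUC (midrank tie handling)
#'
#' The area under the ROC curve computed as the Mann-Whitney statistic: the
#' probability that a randomly chosen positive sample receives a higher score
#' than a randomly chosen negative one, with ties counted 1/2 (midranks,
#' equivalent to the trapezoidal ROC area).
#'
#' @param scores numeric scores, higher = more positive.
#' @param isPositive logical vector marking the positive samples.
#' @return AUC in \[0, 1\].
#' @export
aucRank <- function(scores, isPositive) {
    if (length(scores) != length(isPositive))
        stop("scores and isPositive must have equal length")
    n1 <- sum(isPositive)
    n0 <- sum(!isPositive)
    if (n1 == 0L || n0 == 0L)
        stop("AUC undefined: both classes must be present")
    r <- rank(scores)    # midranks for ties
    (sum(r[isPositive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold metrics and AUC for one evaluation
#'
#' Computes accuracy, precision (positive predictive value), sensitivity
#' (recall), F1 (harmonic mean of precision and sensitivity) and rank-based
#' AUC from scores. Labels are assigned by `score >= threshold`. A metric
#' with a zero denominator (e.g. precision when nothing is predicted
#' positive) is reported as `NA` with a warning — never silently coerced
#' to 0. AUC requires both classes in `yTrue` and errors otherwise.
#'
#' @param yTrue 0/1 labels.
#' @param scores positive-class scores in \[0, 1\].
#' @param threshold decision threshold (ties go to the positive class).
#' @param positiveClass label value treated as positive (default 0,
#'   abnormal).
#' @return named numeric vector
#'   `c(accuracy, precision, sensitivity, f1, auc)`.
#' @examples
#' computeMetrics(c(0,0,1,1), c(0.9, 0.8, 0.2, 0.1))  # perfect: all 1
#' @export
computeMetrics <- function(yTrue, scores, threshold = 0.5,
                           positiveClass = 0L) {
    if (length(yTrue) != length(scores))
        stop("yTrue and scores must have equal length")
    yPred <- ifelse(scores >= threshold, positiveClass, 1L - positiveClass)
    cc <- confusionCounts(yTrue, yPred, positiveClass)
    n <- sum(cc)
    accuracy <- (cc["TP"] + cc["TN"]) / n
    precision <- if (cc["TP"] + cc["FP"] == 0) {
        warning("precision undefined: no samples predicted positive")
        NA_real_
    } else cc["TP"] / (cc["TP"] + cc["FP"])
    sensitivity <- if (cc["TP"] + cc["FN"] == 0) {
        warning("sensitivity undefined: no positive samples present")
        NA_real_
    } else cc["TP"] / (cc["TP"] + cc["FN"])
    f1 <- if (is.na(precision) || is.na(sensitivity) ||
              precision + sensitivity == 0) {
        warning("F1 undefined")
        NA_real_
    } else 2 * precision * sensitivity / (precision + sensitivity)
    auc <- aucRank(scores, yTrue == positiveClass)
    c(accuracy = unname(accuracy), precision = unname(precision),
      sensitivity = unname(sensitivity), f1 = unname(f1), auc = auc)
}

.METRIC_NAMES <- c("accuracy", "precision", "sensitivity", "f1", "auc")

#' Aggregate per-fold metrics into mean and standard deviation
#'
#' Groups the per-fold metric table by model family and partition and
#' reports, per metric, the across-fold mean and standard deviation — the
#' "mean +/- sd" panel of a cross-validation report.
#'
#' @param perFold `data.frame` with columns `model`, `partition`, `fold`,
#'   the five metric columns, and `elapsedSeconds`.
#' @param sdType `"sample"` (n-1 denominator, default) or `"population"`.
#'   A single-fold group gets sd 0 (population convention) with a warning.
#' @return `data.frame` with columns `model`, `partition`, `metric`,
#'   `mean`, `sd`, `nFolds` (metrics plus mean elapsed seconds).
#' @export
aggregateMetrics <- function(perFold, sdType = c("sample", "population")) {
    sdType <- match.arg(sdType)
    if (!is.data.frame(perFold) || nrow(perFold) == 0L)
        stop("perFold must be a non-empty data.frame")
    need <- c("model", "partition", .METRIC_NAMES)
    if (!all(need %in% names(perFold)))
        stop("perFold lacks required columns: ",
             paste(setdiff(need, names(perFold)), collapse = ", "))
    cols <- c(.METRIC_NAMES,
              intersect("elapsedSeconds", names(perFold)))
    groups <- split(perFold,
                    list(perFold$model, perFold$partition), drop = TRUE)
    rows <- lapply(groups, function(g) {
        if (nrow(g) == 1L)
            warning("aggregating a single fold: sd reported as 0")
        do.call(rbind, lapply(cols, function(m) {
            v <- g[[m]]
            s <- if (nrow(g) == 1L) 0 else if (sdType == "sample")
                stats::sd(v) else
                    sqrt(mean((v - mean(v))^2))
            data.frame(model = g$model[1L], partition = g$partition[1L],
                       metric = m, mean = mean(v), sd = s, nFolds = nrow(g))
        }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
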