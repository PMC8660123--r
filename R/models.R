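#' Specify an ensemble classifier
#'
#' @description
#' Four ensemble families share one training/scoring contract: adaptive
#' boosting (weighted decision stumps, multiplicative reweighting of
#' misclassified samples), gradient boosting (stagewise regression trees on
#' the binomial-deviance gradient with Newton leaf updates), random forest
#' (bagged fully-grown trees, delegated to the \pkg{randomForest} package),
#' and extreme gradient boosting (delegated to \pkg{xgboost}).
#'
#' Hyperparameters default to the standard settings of each family's
#' reference implementation and are fully overridable; the effective values
#' are stored in the fitted model and echoed into every cross-validation
#' report. Unknown hyperparameter keys are rejected.
#'
#' @param family one of `"adaptive_boosting"`, `"gradient_boosting"`,
#'   `"random_forest"`, `"extreme_gradient_boosting"`.
#' @param seed integer seed fixing all randomness of the fit.
#' @param params named list of hyperparameter overrides (see
#'   `modelDefaults()` for the valid keys and defaults per family).
#' @return a list of class `ModelSpec`.
#' @examples
#' modelSpec("random_forest", seed = 7, params = list(ntree = 200))
#' @export
modelSpec <- function(family = c("adaptive_boosting", "gradient_boosting",
                                 "random_forest",
                                 "extreme_gradient_boosting"),
                      seed = 1L, params = list()) {
    family <- match.arg(family)
    defaults <- modelDefaults(family)
    unknown <- setdiff(names(params), names(defaults))
    if (length(unknown) > 0L)
        stop("unknown hyperparameter(s) for ", family, ": ",
             paste(unknown, collapse = ", "))
    defaults[names(params)] <- params
    structure(list(family = family, seed = as.integer(seed),
                   params = defaults),
              class = "ModelSpec")
}

#' Default hyperparameters per model family
#'
#' @param family a model family name as in [modelSpec()].
#' @return named list of hyperparameters with their default values.
#' @export
modelDefaults <- function(family) {
    switch(family,
           adaptive_boosting = list(n_estimators = 50L, max_depth = 1L,
                                    learning_rate = 1),
           gradient_boosting = list(n_estimators = 100L, learning_rate = 0.1,
                                    max_depth = 3L, min_split = 10L),
           random_forest = list(ntree = 500L, mtry = 3L, nodesize = 1L),
           extreme_gradient_boosting = list(nrounds = 100L, eta = 0.3,
                                            max_depth = 6L, subsample = 1,
                                            colsample_bytree = 1,
                                            min_child_weight = 1),
           stop("unknown model family: ", family))
}

.asFeatureDF <- function(features) {
    features <- .checkFeatureColumns(features)
    as.data.frame(features[, .FEATURE_NAMES, drop = FALSE])
}

## ---- adaptive boosting: weighted stumps, misclassification reweighting ----

.trainAdaBoost <- function(x, y, params) {
    n <- length(y)
    w <- rep(1 / n, n)
    yf <- factor(y, levels = c(0L, 1L))
    ctrl <- rpart::rpart.control(maxdepth = params$max_depth, cp = 0,
                                 xval = 0, minsplit = 2, minbucket = 1,
                                 maxcompete = 0, maxsurrogate = 0)
    stumps <- list(); alphas <- numeric(0)
    df <- cbind(x, .y = yf)
    for (m in seq_len(params$n_estimators)) {
        fit <- rpart::rpart(.y ~ ., data = df, weights = w * n,
                            method = "class", control = ctrl)
        pred <- predict(fit, df, type = "class")
        miss <- pred != yf
        err <- sum(w[miss])
        if (err >= 0.5) {
            if (length(stumps) == 0L)
                stop("adaptive boosting base learner no better than chance")
            break
        }
        err <- max(err, 1e-10)
        alpha <- params$learning_rate * log((1 - err) / err)
        stumps[[length(stumps) + 1L]] <- fit
        alphas <- c(alphas, alpha)
        if (sum(miss) == 0L)   # perfect stump: ensemble is already decided
            break
        w <- w * exp(alpha * miss)
        w <- w / sum(w)
    }
    list(stumps = stumps, alphas = alphas)
}

.scoreAdaBoost <- function(fit, x) {
    votes <- vapply(fit$stumps, function(s)
        as.numeric(predict(s, x, type = "class") == "1"),
        numeric(nrow(x)))
    votes <- matrix(votes, nrow = nrow(x))
    as.numeric(votes %*% fit$alphas) / sum(fit$alphas)
}

## ---- gradient boosting: binomial deviance, Newton step per leaf ----------

.trainGradBoost <- function(x, y, params) {
    n <- length(y)
    p0 <- min(max(mean(y), 1e-10), 1 - 1e-10)
    F0 <- log(p0 / (1 - p0))
    Fx <- rep(F0, n)
    ctrl <- rpart::rpart.control(maxdepth = params$max_depth, cp = 0,
                                 xval = 0, minsplit = params$min_split,
                                 maxcompete = 0, maxsurrogate = 0)
    trees <- vector("list", params$n_estimators)
    df <- x
    for (m in seq_len(params$n_estimators)) {
        p <- stats::plogis(Fx)
        df$.r <- y - p
        fit <- rpart::rpart(.r ~ ., data = df, method = "anova",
                            control = ctrl)
        # Newton step: replace each leaf's mean residual by
        # sum(residual) / sum(p(1-p)) over the leaf's training samples
        leafRows <- which(fit$frame$var == "<leaf>")
        hess <- pmax(p * (1 - p), 1e-10)
        for (l in leafRows) {
            inLeaf <- fit$where == l
            fit$frame$yval[l] <- sum(df$.r[inLeaf]) / sum(hess[inLeaf])
        }
        Fx <- Fx + params$learning_rate * fit$frame$yval[fit$where]
        trees[[m]] <- fit
    }
    list(F0 = F0, trees = trees, learning_rate = params$learning_rate)
}

.scoreGradBoost <- function(fit, x) {
    Fx <- rep(fit$F0, nrow(x))
    for (tr in fit$trees)
        Fx <- Fx + fit$learning_rate * predict(tr, x)
    stats::plogis(Fx)
}

## ---- training / scoring contract ------------------------------------------

#' Train an ensemble classifier on a feature matrix
#'
#' @param spec a [modelSpec()].
#' @param features the 11-column feature matrix of [buildFeatureMatrix()]
#'   (columns `h1..h5, v1..v5, label`), with both classes present.
#' @param positiveClass the label value treated as the positive class for
#'   scoring; defaults to 0 (abnormal), the clinically relevant finding.
#' @return a `PolarMapModel` object holding the fitted ensemble, the spec
#'   (with effective hyperparameters) and the training-row count. Training is
#'   deterministic given `(spec$seed, features)`.
#' @examples
#' pms <- simulatePolarMaps(10, 10, polarMapConfig(imageSize = 35), seed = 1)
#' fm <- buildFeatureMatrix(pms)
#' model <- trainModel(modelSpec("random_forest"), fm)
#' summary(predictScores(model, fm))
#' @export
trainModel <- function(spec, features, positiveClass = 0L) {
    if (!inherits(spec, "ModelSpec"))
        stop("spec must be created by modelSpec()")
    features <- .checkFeatureColumns(features, requireLabel = TRUE)
    if (nrow(features) < 2L)
        stop("need at least 2 training rows")
    if (!positiveClass %in% c(0L, 1L))
        stop("positiveClass must be 0 or 1")
    labels <- features[, "label"]
    if (!all(labels %in% c(0, 1)))
        stop("labels must be 0 or 1")
    if (length(unique(labels)) < 2L)
        stop("degenerate training set: only one class present")
    y <- as.integer(labels == positiveClass)
    x <- .asFeatureDF(features)
    set.seed(spec$seed)
    fit <- switch(spec$family,
        adaptive_boosting = .trainAdaBoost(x, y, spec$params),
        gradient_boosting = .trainGradBoost(x, y, spec$params),
        random_forest = randomForest::randomForest(
            x = x, y = factor(y, levels = c(0L, 1L)),
            ntree = spec$params$ntree, mtry = spec$params$mtry,
            nodesize = spec$params$nodesize),
        extreme_gradient_boosting = {
            p <- spec$params
            xgboost::xgb.train(
                params = list(objective = "binary:logistic",
                              eta = p$eta, max_depth = p$max_depth,
                              subsample = p$subsample,
                              colsample_bytree = p$colsample_bytree,
                              min_child_weight = p$min_child_weight,
                              nthread = 1L, seed = spec$seed),
                data = xgboost::xgb.DMatrix(
                    as.matrix(x), label = y, nthread = 1L),
                nrounds = p$nrounds, verbose = 0)
        })
    structure(list(fit = fit, spec = spec,
                   positiveClass = as.integer(positiveClass),
                   nTrain = nrow(features)),
              class = "PolarMapModel")
}

#' @export
print.PolarMapModel <- function(x, ...) {
    cat("PolarMapModel:", x$spec$family, "\n")
    cat("  trained on", x$nTrain, "rows; positive class =",
        x$positiveClass, if (x$positiveClass == 0L) "(abnormal)\n"
        else "(normal)\n")
    invisible(x)
}

#' Predict class scores
#'
#' @param model a fitted `PolarMapModel` from [trainModel()].
#' @param features matrix or data.frame with the 10 feature columns
#'   `h1..h5, v1..v5` (a `label` column, if present, is ignored).
#' @return numeric vector in \[0, 1\]: the estimated probability of the
#'   model's positive class, one value per row.
#' @export
predictScores <- function(model, features) {
    if (!inherits(model, "PolarMapModel"))
        stop("model must be a PolarMapModel")
    x <- .asFeatureDF(features)
    s <- switch(model$spec$family,
        adaptive_boosting = .scoreAdaBoost(model$fit, x),
        gradient_boosting = .scoreGradBoost(model$fit, x),
        random_forest = predict(model$fit, x, type = "prob")[, "1"],
        extreme_gradient_boosting = predict(model$fit, as.matrix(x)))
    pmin(pmax(as.numeric(s), 0), 1)
}

#' Predict hard labels
#'
#' A row is assigned the positive class when its score is greater than or
#' equal to `threshold` (ties at the threshold go to the positive class).
#'
#' @inheritParams predictScores
#' @param threshold decision threshold on the positive-class score.
#' @return integer vector of labels in the original 0/1 coding
#'   (1 = normal, 0 = abnormal).
#' @export
predictLabels <- function(model, features, threshold = 0.5) {
    s <- predictScores(model, features)
    pos <- model$positiveClass
    ifelse(s >= threshold, pos, 1L - pos)
}
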