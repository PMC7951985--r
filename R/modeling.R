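#' Random-Forest configuration
#'
#' Hyperparameters of the Random Forest used throughout: number of trees,
#' maximal number of terminal nodes, minimal number of observations in a
#' terminal node, and the number of variables sampled per split. The
#' defaults are deliberately conservative for desk-scale data; [tuneRF()]
#' re-derives them on any config grid by mean test ROC AUC.
#'
#' @param nTrees Number of trees (default 500).
#' @param maxNodes Maximal number of terminal nodes per tree (default 512).
#' @param minNodeSize Minimal observations in a terminal node (default 30).
#' @param mtry Variables sampled per split; \code{NULL} (default) means
#'   \code{ceiling(sqrt(p))} at fit time.
#' @param seed Integer seed controlling the fit (default 1).
#' @return A list with class \code{"RFConfig"}.
#' @export
rfConfig <- function(nTrees = 500L, maxNodes = 512L, minNodeSize = 30L,
                     mtry = NULL, seed = 1L) {
    stopifnot(nTrees >= 1L, maxNodes >= 1L, minNodeSize >= 1L,
              is.null(mtry) || mtry >= 1L)
    structure(list(nTrees = as.integer(nTrees),
                   maxNodes = as.integer(maxNodes),
                   minNodeSize = as.integer(minNodeSize),
                   mtry = if (is.null(mtry)) NULL else as.integer(mtry),
                   seed = as.integer(seed)),
              class = "RFConfig")
}

#' Repeated stratified train/test split plan
#'
#' @param nRepeats Number of independent splits (default 30).
#' @param testFraction Fraction of rows in the test set (default 0.3).
#' @param seed Base seed; repeat \code{r} uses \code{seed + r}.
#' @return A list with class \code{"SplitPlan"}.
#' @export
splitPlan <- function(nRepeats = 30L, testFraction = 0.3, seed = 1L) {
    stopifnot(nRepeats >= 1L, testFraction > 0, testFraction < 1)
    structure(list(nRepeats = as.integer(nRepeats),
                   testFraction = testFraction, seed = as.integer(seed)),
              class = "SplitPlan")
}

.strata <- function(win, y) {
    # chromosome x positional tercile x class; strata with < 4 rows collapse
    # to chromosome x class
    chr <- as.character(seqnames(win))
    terc <- integer(length(chr))
    for (ch in unique(chr)) {
        idx <- which(chr == ch)
        r <- rank(start(win)[idx], ties.method = "first")
        terc[idx] <- as.integer(cut(r, breaks = 3, labels = FALSE))
    }
    full <- paste(chr, terc, y, sep = "|")
    small <- names(which(table(full) < 4L))
    key <- full
    key[full %in% small] <- paste(chr, y, sep = "|")[full %in% small]
    key
}

#' Repeated stratified train/test splits
#'
#' Generates \code{nRepeats} random partitions of the retained-window rows
#' into train and test, stratified by chromosome, position within the
#' chromosome (terciles) and class label, so that test sets preserve both
#' the genomic spread and the class imbalance. Strata smaller than 4 rows
#' collapse to chromosome-by-class; a singleton stratum always goes to
#' train. Deterministic for a fixed base seed.
#'
#' @param grid A [WindowGrid-class].
#' @param y Class labels aligned to [retainedWindows()] (or to \code{rows}).
#' @param plan A [splitPlan()].
#' @param rows Optional integer subset of rows being modeled (indices into
#'   the retained windows); defaults to all.
#' @return A list of \code{nRepeats} lists with integer elements
#'   \code{train}, \code{test} (indices into \code{seq_along(y)}).
#' @export
makeSplits <- function(grid, y, plan = splitPlan(), rows = NULL) {
    win <- retainedWindows(grid)
    if (is.null(rows)) rows <- seq_along(win)
    win <- win[rows]
    stopifnot(length(y) == length(win))
    cls <- unique(y)
    if (length(cls) < 2L)
        stop(sprintf("class '%s' is entirely absent",
                     if (is.logical(y) || is.numeric(y))
                         format(setdiff(c(0, 1), as.numeric(cls))[1])
                     else "other"))
    key <- .strata(win, y)
    n <- length(y)
    lapply(seq_len(plan$nRepeats), function(r) {
        set.seed(plan$seed + r)
        test <- integer(0)
        for (k in unique(key)) {
            idx <- which(key == k)
            nTest <- round(plan$testFraction * length(idx))
            if (length(idx) == 1L) nTest <- 0L
            if (nTest > 0L)
                test <- c(test, sample(idx, nTest))
        }
        test <- sort(test)
        list(train = setdiff(seq_len(n), test), test = test)
    })
}

.rfSeed <- function(config) if (is.null(config$seed)) 1L else config$seed

#' Fit the Random-Forest hotspot classifier
#'
#' Fits a probability-scoring Random Forest. Importances are impurity
#' (Gini) decreases normalized to sum to one. Refitting with the same data,
#' config and seed reproduces scores bit-identically.
#'
#' @param X Numeric matrix (rows = windows, cols = features).
#' @param y Binary labels (logical or 0/1), both classes present.
#' @param config An [rfConfig()].
#' @return A \code{FittedModel} list: \code{fit}, \code{importance}
#'   (normalized, named), \code{config}, \code{type = "classification"}.
#' @export
fitClassifier <- function(X, y, config = rfConfig()) {
    X <- as.matrix(X)
    y <- as.integer(y)
    if (length(unique(y)) < 2L)
        stop("need both classes in y")
    if (all(apply(X, 2, function(v) length(unique(v)) == 1L))) {
        # no split is possible; return the prevalence scorer rather than
        # handing the forest an unsplittable matrix
        warning("all feature columns are constant; fitting a constant model")
        p <- ncol(X)
        return(structure(list(fit = NULL, constant = mean(y),
                              importance = stats::setNames(rep(1 / p, p),
                                                           colnames(X)),
                              config = config, type = "classification"),
                         class = "FittedModel"))
    }
    mtry <- if (is.null(config$mtry)) ceiling(sqrt(ncol(X))) else
        min(config$mtry, ncol(X))
    set.seed(.rfSeed(config))
    fit <- randomForest::randomForest(
        x = X, y = factor(y, levels = c(0, 1)),
        ntree = config$nTrees, maxnodes = min(config$maxNodes, nrow(X)),
        nodesize = config$minNodeSize, mtry = mtry)
    imp <- fit$importance[, "MeanDecreaseGini"]
    s <- sum(imp)
    imp <- if (s > 0) imp / s else rep(1 / length(imp), length(imp))
    structure(list(fit = fit, importance = imp, config = config,
                   type = "classification"),
              class = "FittedModel")
}

#' Predict scores from a fitted model
#'
#' @param object A \code{FittedModel}.
#' @param newdata Numeric feature matrix.
#' @param ... Unused.
#' @return For classifiers, the positive-class probability in \[0, 1\]; for
#'   regressors, predictions on the transformed target scale.
#' @export
predict.FittedModel <- function(object, newdata, ...) {
    newdata <- as.matrix(newdata)
    if (!is.null(object$constant))
        return(rep(object$constant, nrow(newdata)))
    if (object$type == "classification") {
        unname(stats::predict(object$fit, newdata, type = "prob")[, "1"])
    } else {
        unname(stats::predict(object$fit, log2(1 + newdata)))
    }
}

#' Fit the Random-Forest density regressor
#'
#' Regression of per-window breakpoint density on feature densities with the
#' transforms used in the state-of-the-art comparison protocol:
#' \code{log2(1 + x)} for features and \code{log2(mean(y) + y)} for the
#' target. Predictions and R-squared are on the transformed target scale.
#'
#' @param X Numeric feature matrix (raw densities, >= 0).
#' @param y Numeric breakpoint densities (>= 0), not all zero.
#' @param config An [rfConfig()].
#' @return A \code{FittedModel} with \code{type = "regression"} and the
#'   stored target offset \code{yMean}.
#' @export
fitRegressor <- function(X, y, config = rfConfig()) {
    X <- as.matrix(X)
    if (any(y < 0)) stop("densities must be non-negative")
    if (all(y == 0)) stop("target is all zero")
    yMean <- mean(y)
    yt <- log2(yMean + y)
    mtry <- if (is.null(config$mtry)) max(1L, floor(ncol(X) / 3)) else
        min(config$mtry, ncol(X))
    set.seed(.rfSeed(config))
    fit <- randomForest::randomForest(
        x = log2(1 + X), y = yt,
        ntree = config$nTrees, maxnodes = min(config$maxNodes, nrow(X)),
        nodesize = config$minNodeSize, mtry = mtry)
    structure(list(fit = fit, importance = {
        imp <- fit$importance[, "IncNodePurity"]
        s <- sum(imp); if (s > 0) imp / s else rep(1 / length(imp), length(imp))
    }, config = config, type = "regression", yMean = yMean),
              class = "FittedModel")
}

#' Transform a raw density target to the regression scale
#' @param y Raw densities.
#' @param yMean Offset, typically \code{mean(y)} of the training target.
#' @return \code{log2(yMean + y)}.
#' @export
transformTarget <- function(y, yMean) log2(yMean + y)

#' Fit logistic regression and its intercept-only null
#'
#' Maximum-likelihood logistic fits used for McFadden pseudo R-squared.
#' Perfect separation is flagged (attribute \code{separation}) but the
#' likelihoods at the optimizer's stopping point are still returned.
#'
#' @param X Numeric feature matrix.
#' @param y Binary labels, both classes present.
#' @return List with \code{llModel}, \code{llNull}, \code{model},
#'   \code{separation}.
#' @export
fitLogistic <- function(X, y) {
    y <- as.integer(y)
    if (length(unique(y)) < 2L) stop("need both classes in y")
    df <- data.frame(y = y, as.data.frame(as.matrix(X)))
    sep <- FALSE
    fit <- withCallingHandlers(
        stats::glm(y ~ ., data = df, family = stats::binomial()),
        warning = function(w) {
            if (grepl("numerically 0 or 1|did not converge", conditionMessage(w)))
                sep <<- TRUE
            invokeRestart("muffleWarning")
        })
    # glm does not always warn on separation (small n converges quietly);
    # flag fitted probabilities pinned to 0/1 directly
    if (any(stats::fitted(fit) > 1 - 1e-7) || any(stats::fitted(fit) < 1e-7))
        sep <- TRUE
    null <- stats::glm(y ~ 1, data = df, family = stats::binomial())
    list(llModel = as.numeric(stats::logLik(fit)),
         llNull = as.numeric(stats::logLik(null)),
         model = fit, separation = sep)
}

#' Save or load a fitted model archive
#'
#' The archive stores the predictor, its normalized importances and the
#' config it was fitted with.
#'
#' @param model A \code{FittedModel}.
#' @param path Archive path.
#' @return \code{saveModel}: the path, invisibly; \code{loadModel}: the
#'   \code{FittedModel}.
#' @export
saveModel <- function(model, path) {
    stopifnot(inherits(model, "FittedModel"))
    saveRDS(model, path)
    invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
    model <- readRDS(path)
    stopifnot(inherits(model, "FittedModel"))
    model
}

#' Tune Random-Forest hyperparameters over a config grid
#'
#' Evaluates every configuration on every dataset (mean test ROC AUC over
#' the dataset's splits) and returns the configuration maximizing the grand
#' mean across datasets. Ties are broken toward smaller models (fewer trees,
#' then fewer terminal nodes).
#'
#' @param configs List of [rfConfig()]s.
#' @param datasets List of lists, each with \code{X}, \code{y},
#'   \code{splits} (as from [makeSplits()]).
#' @return The winning \code{RFConfig} with attribute \code{"score"}.
#' @export
tuneRF <- function(configs, datasets) {
    if (length(configs) == 0L) stop("empty config grid")
    stopifnot(length(datasets) >= 1L)
    scores <- vapply(configs, function(cfg) {
        mean(vapply(datasets, function(d) {
            mean(vapply(d$splits, function(sp) {
                m <- fitClassifier(d$X[sp$train, , drop = FALSE],
                                   d$y[sp$train], cfg)
                rocAUC(d$y[sp$test],
                       predict(m, d$X[sp$test, , drop = FALSE]))
            }, 0))
        }, 0))
    }, 0)
    size <- vapply(configs, function(cfg) cfg$nTrees * 1e6 + cfg$maxNodes, 0)
    best <- order(-scores, size)[1L]
    out <- configs[[best]]
    attr(out, "score") <- scores[best]
    out
}
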