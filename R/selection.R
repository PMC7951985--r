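.borutaSeed <- function(seed, i) (as.integer(seed) + 104729L * i) %% 2147483647L

.rfImportance <- function(X, y, config, usePermutation = FALSE) {
    mtry <- if (is.null(config$mtry)) ceiling(sqrt(ncol(X))) else
        min(config$mtry, ncol(X))
    set.seed(.rfSeed(config))
    fit <- randomForest::randomForest(
        x = X, y = factor(y, levels = c(0, 1)),
        ntree = config$nTrees, maxnodes = min(config$maxNodes, nrow(X)),
        nodesize = config$minNodeSize, mtry = mtry,
        importance = usePermutation)
    if (usePermutation) {
        # scaled OOB permutation importance (Z-score over trees), the
        # statistic the original shadow-feature procedure tests
        imp <- randomForest::importance(fit, type = 1, scale = TRUE)[, 1]
        imp[is.nan(imp)] <- 0
        imp
    } else fit$importance[, "MeanDecreaseGini"]
}

#' Boruta shadow-feature selection
#'
#' Iteratively tests every feature against randomized "shadow" copies of the
#' feature set. Each iteration appends one column-wise permuted shadow per
#' remaining real feature, fits a Random Forest on the combined matrix, and
#' scores a hit for every real feature whose importance strictly exceeds the
#' maximum shadow importance. After each iteration a two-sided binomial test
#' (success probability 0.5, Bonferroni-corrected at level \code{alpha}
#' across the currently undecided features) confirms features with
#' significantly many hits and rejects those with significantly few;
#' rejected features and all shadows are dropped before the next iteration
#' (the shadow pool is padded to at least five columns when few real
#' features remain, so the max-shadow reference never collapses). Features
#' still undecided at \code{maxIter} are tentative.
#'
#' The importance statistic is the out-of-bag permutation importance scaled
#' by its SD over trees. Impurity (Gini) importance is available via
#' \code{usePermutation = FALSE} but is not recommended as the decision
#' statistic: the feature most spuriously correlated with a given label
#' vector beats fresh shadows on Gini importance persistently, which
#' inflates false confirmations on uninformative data.
#'
#' @param X Numeric feature matrix with >= 2 named columns.
#' @param y Binary labels, both classes present.
#' @param config An [rfConfig()] for the internal forests.
#' @param alpha Significance level (default 0.05).
#' @param maxIter Maximum iterations (default 100).
#' @param seed Integer seed driving shadow permutations and forest fits.
#' @param usePermutation Use scaled permutation importance (default) rather
#'   than impurity importance.
#' @return A data.frame with one row per feature: \code{feature},
#'   \code{status} in \{confirmed, tentative, rejected\}, \code{hits},
#'   \code{iterations}.
#' @export
boruta <- function(X, y, config = rfConfig(), alpha = 0.05, maxIter = 100L,
                   seed = 1L, usePermutation = TRUE) {
    X <- as.matrix(X)
    if (ncol(X) < 2L) stop("need at least 2 features")
    if (maxIter < 1L) stop("maxIter must be >= 1")
    y <- as.integer(y)
    if (length(unique(y)) < 2L) stop("need both classes in y")
    feats <- colnames(X)
    if (is.null(feats)) feats <- colnames(X) <- paste0("f", seq_len(ncol(X)))
    status <- stats::setNames(rep("undecided", length(feats)), feats)
    hits <- stats::setNames(integer(length(feats)), feats)
    iter <- 0L
    while (iter < maxIter && any(status == "undecided")) {
        iter <- iter + 1L
        remaining <- feats[status != "rejected"]
        Xr <- X[, remaining, drop = FALSE]
        set.seed(.borutaSeed(seed, iter))
        shadow <- apply(Xr, 2, sample)
        colnames(shadow) <- paste0(".shadow.", remaining)
        # keep at least 5 shadows (duplicated permuted copies when few real
        # features remain): with one or two shadows the max-shadow reference
        # collapses and null features start scoring hits at rate ~1/2
        k <- 0L
        while (ncol(shadow) < 5L) {
            k <- k + 1L
            j <- ((k - 1L) %% ncol(Xr)) + 1L
            extra <- matrix(sample(Xr[, j]), ncol = 1,
                            dimnames = list(NULL, paste0(".shadow.dup", k)))
            shadow <- cbind(shadow, extra)
        }
        cfg <- config
        cfg$seed <- .borutaSeed(seed, iter) %% 1000000L
        imp <- .rfImportance(cbind(Xr, shadow), y, cfg, usePermutation)
        shadowMax <- max(imp[colnames(shadow)])
        hit <- imp[remaining] > shadowMax
        hits[remaining] <- hits[remaining] + as.integer(hit)
        undecided <- feats[status == "undecided"]
        m <- length(undecided)
        for (f in undecided) {
            pHigh <- stats::pbinom(hits[f] - 1L, iter, 0.5, lower.tail = FALSE)
            pLow <- stats::pbinom(hits[f], iter, 0.5)
            if (pHigh < alpha / m) status[f] <- "confirmed"
            else if (pLow < alpha / m) status[f] <- "rejected"
        }
    }
    status[status == "undecided"] <- "tentative"
    data.frame(feature = feats, status = unname(status),
               hits = unname(hits), iterations = iter,
               stringsAsFactors = FALSE)
}

#' Greedy forward feature selection
#'
#' Starting from a base feature set, repeatedly adds the candidate that
#' maximizes the mean test ROC AUC over the supplied splits, stopping when
#' the best improvement falls below \code{tolerance} or the criterion
#' reaches the all-features reference (base plus all candidates, computed
#' internally unless supplied).
#'
#' @param X Numeric feature matrix with named columns.
#' @param y Binary labels.
#' @param base Character vector of base feature names (may be empty; an
#'   empty model scores 0.5).
#' @param candidates Character vector of candidate names, disjoint from
#'   \code{base}.
#' @param splits Splits from [makeSplits()].
#' @param config An [rfConfig()].
#' @param tolerance Minimum improvement to keep adding (default 0.005).
#' @param reference Optional criterion ceiling; default is the base-plus-
#'   all-candidates model.
#' @return Character vector of added features (possibly empty), with the
#'   criterion trajectory as attribute \code{"criterion"}.
#' @export
forwardSelect <- function(X, y, base, candidates, splits,
                          config = rfConfig(), tolerance = 0.005,
                          reference = NULL) {
    if (length(intersect(base, candidates)))
        stop("base and candidates must be disjoint")
    if (length(candidates) == 0L) return(character())
    X <- as.matrix(X)
    crit <- function(set) {
        if (length(set) == 0L) return(0.5)
        mean(vapply(splits, function(sp) {
            m <- fitClassifier(X[sp$train, set, drop = FALSE],
                               y[sp$train], config)
            rocAUC(y[sp$test], predict(m, X[sp$test, set, drop = FALSE]))
        }, 0))
    }
    if (is.null(reference)) reference <- crit(c(base, candidates))
    current <- crit(base)
    added <- character()
    trace <- current
    pool <- candidates
    while (length(pool) && current < reference) {
        vals <- vapply(pool, function(f) crit(c(base, added, f)), 0)
        best <- order(-vals, pool)[1L]
        if (vals[best] - current < tolerance) break
        added <- c(added, pool[best])
        current <- vals[best]
        trace <- c(trace, current)
        pool <- pool[-best]
    }
    attr(added, "criterion") <- trace
    added
}

#' Scale and rank feature-group scores across labeling types
#'
#' For each labeling type the groups' mean lifts of recall are scaled to the
#' maximum achieved by any group for that type; the scaled values are then
#' averaged per group across the two types and ranked descending (ties
#' broken by group name). If every group has zero lift for a labeling type,
#' all scaled scores for that type are 0.
#'
#' @param lifts Numeric matrix: rows = feature groups (rownames required),
#'   columns = labeling types (e.g. \code{"99"}, \code{"99.5"}).
#' @return A data.frame with \code{group}, \code{score} in \[0, 1\],
#'   \code{rank}.
#' @export
scaleGroupScores <- function(lifts) {
    lifts <- as.matrix(lifts)
    stopifnot(nrow(lifts) >= 1L, !is.null(rownames(lifts)))
    scaled <- apply(lifts, 2, function(v) {
        mx <- max(v)
        if (mx <= 0) rep(0, length(v)) else v / mx
    })
    scaled <- matrix(scaled, nrow = nrow(lifts),
                     dimnames = dimnames(lifts))
    score <- rowMeans(scaled)
    ord <- order(-score, rownames(lifts))
    data.frame(group = rownames(lifts)[ord], score = unname(score[ord]),
               rank = seq_along(score), stringsAsFactors = FALSE)
}

#' Rank features by confirmation frequency across Boruta runs
#'
#' Counts, across a collection of Boruta results (e.g. all splits, cancer
#' types and labeling types), how often each feature was confirmed, and
#' returns those confirmed in at least the threshold fraction of runs,
#' ranked by count.
#'
#' @param results List of data.frames from [boruta()].
#' @param threshold Minimum confirmation fraction (default 0.1, the
#'   at-least-300-of-3000 criterion).
#' @return A data.frame with \code{feature}, \code{nConfirmed},
#'   \code{fraction}, \code{rank}; empty if \code{results} is empty.
#' @export
importanceFrequency <- function(results, threshold = 0.1) {
    empty <- data.frame(feature = character(), nConfirmed = integer(),
                        fraction = numeric(), rank = integer(),
                        stringsAsFactors = FALSE)
    if (length(results) == 0L) return(empty)
    conf <- unlist(lapply(results, function(r)
        r$feature[r$status == "confirmed"]))
    if (length(conf) == 0L) return(empty)
    tab <- table(conf)
    frac <- as.numeric(tab) / length(results)
    keep <- frac >= threshold
    if (!any(keep)) return(empty)
    feat <- names(tab)[keep]
    cnt <- as.integer(tab)[keep]
    ord <- order(-cnt, feat)
    data.frame(feature = feat[ord], nConfirmed = cnt[ord],
               fraction = frac[keep][ord], rank = seq_along(ord),
               stringsAsFactors = FALSE)
}
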