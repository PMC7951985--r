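#' Select the top-scoring fraction of windows
#'
#' Selects exactly \code{ceiling(p * n)} rows with the highest scores; ties
#' are broken by ascending id so the selection is deterministic.
#'
#' @param scores Numeric score vector.
#' @param p Fraction in (0, 1) — the probability percentile of the lift
#'   metrics (e.g. 0.03, 0.05, 0.1).
#' @param ids Optional tie-break ids (default \code{seq_along(scores)}).
#' @return Integer indices of the selected rows.
#' @export
selectTop <- function(scores, p, ids = seq_along(scores)) {
    if (length(scores) == 0L) stop("empty scores")
    if (p <= 0 || p >= 1) stop("p must lie in (0, 1)")
    k <- ceiling(p * length(scores))
    order(-scores, ids)[seq_len(k)]
}

#' Lift of recall at a probability percentile
#'
#' Recall among the top-\code{p} fraction of windows by score, divided by
#' \code{p} — the recall a random ranking attains in expectation when
#' labeling a \code{p}-fraction of windows. Values above 1 mean the model
#' concentrates true hotspots in its top predictions better than chance;
#' the maximum is \code{min(1/p, 1/prevalence)}.
#'
#' @param y Binary labels with at least one positive.
#' @param scores Numeric scores aligned to \code{y}.
#' @param p Probability percentile in (0, 1).
#' @param ids Optional tie-break ids.
#' @return Numeric lift (>= 0).
#' @export
liftOfRecall <- function(y, scores, p, ids = seq_along(scores)) {
    y <- as.integer(y)
    if (sum(y) == 0L) stop("no positives in y")
    top <- selectTop(scores, p, ids)
    recall <- sum(y[top]) / sum(y)
    recall / p
}

#' Lift of precision at a probability percentile
#'
#' Precision among the top-\code{p} fraction divided by the prevalence of
#' positives — the precision of random guessing. Shows how many times the
#' model beats random guessing among its top predictions.
#'
#' @inheritParams liftOfRecall
#' @return Numeric lift (>= 0).
#' @export
liftOfPrecision <- function(y, scores, p, ids = seq_along(scores)) {
    y <- as.integer(y)
    if (sum(y) == 0L) stop("no positives in y")
    top <- selectTop(scores, p, ids)
    precision <- sum(y[top]) / length(top)
    precision / mean(y)
}

#' ROC AUC with the pair-probability tie convention
#'
#' \code{P(score+ > score-) + 0.5 P(tie)} over all positive-negative pairs,
#' computed by the rank (Mann-Whitney) identity.
#'
#' @param y Binary labels, both classes present.
#' @param scores Numeric scores.
#' @return AUC in \[0, 1\].
#' @export
rocAUC <- function(y, scores) {
    y <- as.integer(y)
    n1 <- sum(y == 1L); n0 <- sum(y == 0L)
    if (n1 == 0L || n0 == 0L) stop("need both classes in y")
    r <- rank(scores, ties.method = "average")
    (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision-recall AUC (step interpolation)
#'
#' Area under the precision-recall curve by step interpolation: the sum over
#' positives, in score order, of the precision at their rank, divided by the
#' number of positives (average precision). Ties are ordered deterministically
#' by ascending index.
#'
#' @inheritParams rocAUC
#' @return PR AUC in \[0, 1\].
#' @export
prAUC <- function(y, scores) {
    y <- as.integer(y)
    if (sum(y) == 0L || sum(y == 0L) == 0L) stop("need both classes in y")
    o <- order(-scores, seq_along(scores))
    yo <- y[o]
    tp <- cumsum(yo)
    prec <- tp / seq_along(yo)
    sum(prec[yo == 1L]) / sum(yo)
}

#' McFadden pseudo R-squared
#'
#' \code{1 - llModel / llNull}: 0 when the model explains nothing beyond the
#' intercept, approaching 1 as the model log-likelihood approaches 0.
#'
#' @param llModel Log-likelihood of the fitted model (<= 0).
#' @param llNull Log-likelihood of the intercept-only null (< 0).
#' @return Numeric pseudo R-squared.
#' @export
mcfaddenR2 <- function(llModel, llNull) {
    if (llNull >= 0) stop("llNull must be negative")
    if (llModel > 0) stop("llModel must be non-positive")
    1 - llModel / llNull
}

#' Mean Spearman correlation between two models' predictions
#'
#' Rank correlation per split, averaged over splits. A split on which either
#' prediction vector is constant has an undefined correlation and is skipped
#' with a warning.
#'
#' @param predsA,predsB Lists of aligned numeric prediction vectors, one per
#'   split.
#' @return Mean Spearman rho over the usable splits.
#' @export
predictionCorrelation <- function(predsA, predsB) {
    stopifnot(length(predsA) == length(predsB))
    rho <- vapply(seq_along(predsA), function(i) {
        a <- predsA[[i]]; b <- predsB[[i]]
        if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
        stats::cor(a, b, method = "spearman")
    }, 0)
    if (anyNA(rho)) {
        warning(sprintf("%d split(s) with constant predictions skipped",
                        sum(is.na(rho))))
        rho <- rho[!is.na(rho)]
    }
    mean(rho)
}

#' Precision by cross-group agreement level
#'
#' Each feature group contributes its top-fraction selection of windows;
#' every selected window is assigned the number of groups that selected it,
#' and the fraction of true hotspots is reported per agreement level.
#'
#' @param scoreList Named list of per-group score vectors, aligned to
#'   \code{y}.
#' @param y Binary truth labels.
#' @param top Selection fraction per group (default 0.05).
#' @return A data.frame with \code{agreement}, \code{nSelected},
#'   \code{nTrue}, \code{precision}.
#' @export
overlapPrecision <- function(scoreList, y, top = 0.05) {
    stopifnot(length(scoreList) >= 2L)
    y <- as.integer(y)
    counts <- integer(length(y))
    for (s in scoreList) {
        sel <- selectTop(s, top)
        counts[sel] <- counts[sel] + 1L
    }
    levs <- seq_len(length(scoreList))
    do.call(rbind, lapply(levs, function(a) {
        idx <- which(counts == a)
        data.frame(agreement = a, nSelected = length(idx),
                   nTrue = sum(y[idx]),
                   precision = if (length(idx)) mean(y[idx]) else NA_real_)
    }))
}

#' Per-split metric rows for one test set
#'
#' Computes the full metric suite for one split's test predictions: ROC AUC,
#' PR AUC, and recall/precision with their lifts at the probability
#' percentiles. If the test labels are single-class (possible at extreme
#' labeling thresholds) every metric is undefined and the row is NA;
#' [aggregateMetrics()] drops such splits.
#'
#' @param y Binary test labels.
#' @param scores Test scores.
#' @param percentiles Probability percentiles (default
#'   \code{c(0.03, 0.05, 0.1)}).
#' @return A one-row data.frame.
#' @export
splitMetrics <- function(y, scores, percentiles = c(0.03, 0.05, 0.1)) {
    y <- as.integer(y)
    degenerate <- length(unique(y)) < 2L
    out <- if (degenerate)
        data.frame(roc_auc = NA_real_, pr_auc = NA_real_)
    else data.frame(roc_auc = rocAUC(y, scores), pr_auc = prAUC(y, scores))
    for (p in percentiles) {
        tag <- sub("^0\\.", "", format(p))
        if (degenerate) {
            for (m in c("recall_p", "precision_p", "lift_recall_p",
                        "lift_precision_p"))
                out[[paste0(m, tag)]] <- NA_real_
            next
        }
        top <- selectTop(scores, p)
        recall <- sum(y[top]) / sum(y)
        precision <- sum(y[top]) / length(top)
        out[[paste0("recall_p", tag)]] <- recall
        out[[paste0("precision_p", tag)]] <- precision
        out[[paste0("lift_recall_p", tag)]] <- recall / p
        out[[paste0("lift_precision_p", tag)]] <- precision / mean(y)
    }
    out
}

#' Aggregate a per-split metric report
#'
#' Mean, median and the 95% normal-approximation confidence interval of the
#' mean (mean ± 1.96 sd / sqrt(repeats)) for every metric column.
#'
#' @param report Data.frame of per-split metric rows ([splitMetrics()]).
#' @return Data.frame with one row per metric: \code{metric}, \code{mean},
#'   \code{median}, \code{ciLow}, \code{ciHigh}.
#' @export
aggregateMetrics <- function(report) {
    do.call(rbind, lapply(colnames(report), function(m) {
        v <- report[[m]]
        v <- v[!is.na(v)]     # splits with a single-class test set
        n <- length(v)
        se <- stats::sd(v) / sqrt(n)
        data.frame(metric = m, mean = mean(v), median = stats::median(v),
                   ciLow = mean(v) - 1.96 * se, ciHigh = mean(v) + 1.96 * se)
    }))
}
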