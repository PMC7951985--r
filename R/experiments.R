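#' Specify a modeling task
#'
#' @param kind Target kind: \code{"hotspot_vs_all"} (hotspots against the
#'   rest of the genome), \code{"breakpoint_vs_all"} (breakpoint presence),
#'   \code{"hotspot_vs_breakpoint"} (hotspots against other
#'   breakpoint-carrying windows), or \code{"density_regression"}.
#' @param q Labeling threshold percentile (required unless
#'   \code{density_regression}).
#' @param cancerType Cancer type label; default: the bundle's single type.
#' @param groups,scales,features Optional feature-subset restrictions
#'   (passed to [selectFeatures()]).
#' @return A list with class \code{"TaskSpec"}.
#' @export
taskSpec <- function(kind = c("hotspot_vs_all", "breakpoint_vs_all",
                              "hotspot_vs_breakpoint", "density_regression"),
                     q = NULL, cancerType = NULL, groups = NULL,
                     scales = NULL, features = NULL) {
    kind <- match.arg(kind)
    if (is.null(q) && kind %in% c("hotspot_vs_all", "hotspot_vs_breakpoint"))
        stop("q is required for hotspot tasks")
    structure(list(kind = kind, q = q, cancerType = cancerType,
                   groups = groups, scales = scales, features = features),
              class = "TaskSpec")
}

.taskLabels <- function(task, bundle) {
    labels <- bundle$labels
    ct <- task$cancerType
    if (is.null(ct)) ct <- unique(labels$cancer_type)[1]
    sub <- labels[labels$cancer_type == ct, ]
    sub <- sub[order(sub$window_id), ]
    win <- retainedWindows(bundle$grid)
    stopifnot(all(sub$window_id == mcols(win)$window_id))
    rows <- seq_len(nrow(sub))
    if (task$kind == "density_regression") {
        y <- sub$density
    } else if (task$kind == "breakpoint_vs_all") {
        y <- as.integer(sub$presence)
    } else {
        col <- hotspotColumn(task$q)
        if (!col %in% colnames(sub))
            stop("label column absent from bundle: ", col)
        if (task$kind == "hotspot_vs_breakpoint") {
            rows <- which(sub$presence)
            y <- as.integer(sub[[col]][rows])
        } else {
            y <- as.integer(sub[[col]])
        }
    }
    list(y = y, rows = rows, cancerType = ct)
}

.taskMatrix <- function(task, bundle) {
    featureValues(selectFeatures(bundle$fm, groups = task$groups,
                                 scales = task$scales,
                                 features = task$features))
}

#' Run one modeling task over repeated splits
#'
#' Fits the Random Forest on every train split, scores the matching test
#' split, and collects the full metric suite per split plus the cached test
#' predictions (for downstream correlation and overlap analyses). Fully
#' reproducible from (bundle, task, plan, config).
#'
#' @param task A [taskSpec()].
#' @param bundle An analysis bundle (see [simulateBundle()] /
#'   [readBundle()]).
#' @param plan A [splitPlan()].
#' @param config An [rfConfig()].
#' @param splits Optional pre-computed splits (to pair arms across tasks).
#' @return List: \code{task}, \code{report} (per-split data.frame),
#'   \code{aggregate} ([aggregateMetrics()]), \code{predictions} (per split:
#'   \code{row}, \code{window_id}, \code{y}, \code{score}), \code{splits}.
#' @export
runTask <- function(task, bundle, plan = splitPlan(), config = rfConfig(),
                    splits = NULL) {
    tl <- .taskLabels(task, bundle)
    X <- .taskMatrix(task, bundle)[tl$rows, , drop = FALSE]
    win <- retainedWindows(bundle$grid)
    wid <- mcols(win)$window_id[tl$rows]
    if (task$kind == "density_regression") {
        if (is.null(splits))
            splits <- makeSplits(bundle$grid,
                                 as.integer(tl$y > stats::median(tl$y)),
                                 plan, rows = tl$rows)
        rows <- lapply(seq_along(splits), function(i) {
            sp <- splits[[i]]
            m <- fitRegressor(X[sp$train, , drop = FALSE], tl$y[sp$train],
                              config)
            pred <- predict(m, X[sp$test, , drop = FALSE])
            yt <- transformTarget(tl$y[sp$test], m$yMean)
            data.frame(split = i,
                       r2 = 1 - sum((pred - yt)^2) / sum((yt - mean(yt))^2))
        })
        report <- do.call(rbind, rows)
        return(list(task = task, report = report,
                    aggregate = aggregateMetrics(report["r2"]),
                    predictions = NULL, splits = splits))
    }
    if (is.null(splits))
        splits <- makeSplits(bundle$grid, tl$y, plan, rows = tl$rows)
    preds <- vector("list", length(splits))
    rows <- vector("list", length(splits))
    for (i in seq_along(splits)) {
        sp <- splits[[i]]
        cfg <- config
        cfg$seed <- config$seed + i
        m <- fitClassifier(X[sp$train, , drop = FALSE], tl$y[sp$train], cfg)
        score <- predict(m, X[sp$test, , drop = FALSE])
        rows[[i]] <- cbind(split = i, splitMetrics(tl$y[sp$test], score))
        preds[[i]] <- data.frame(row = sp$test, window_id = wid[sp$test],
                                 y = tl$y[sp$test], score = score)
    }
    report <- do.call(rbind, rows)
    list(task = task, report = report,
         aggregate = aggregateMetrics(report[, -1]),
         predictions = preds, splits = splits)
}

#' Randomness experiment suite
#'
#' Builds, at every applicable labeling threshold, the hotspot-vs-all and
#' hotspot-vs-breakpoint discrimination models plus one breakpoint-vs-all
#' model, and tabulates the median test ROC AUC and median lift of recall at
#' the 0.03 probability percentile — the comparison used to assess how
#' random the breakpoint landscape is. Tasks whose labeling yields a single
#' class are skipped with a warning.
#'
#' @param bundle An analysis bundle.
#' @param thresholds Labeling percentiles (default
#'   \code{c(75, 90, 95, 99, 99.5, 99.9)}).
#' @param plan A [splitPlan()].
#' @param config An [rfConfig()].
#' @return List: \code{results} (named list of [runTask()] outputs),
#'   \code{table} (data.frame \code{task}, \code{q}, \code{median_roc_auc},
#'   \code{median_lift_recall_p03}).
#' @export
runRandomnessSuite <- function(bundle,
                               thresholds = c(75, 90, 95, 99, 99.5, 99.9),
                               plan = splitPlan(), config = rfConfig()) {
    tasks <- list(list(kind = "breakpoint_vs_all", q = NA))
    for (q in thresholds) {
        tasks <- c(tasks, list(list(kind = "hotspot_vs_all", q = q),
                               list(kind = "hotspot_vs_breakpoint", q = q)))
    }
    results <- list(); tab <- list()
    for (t in tasks) {
        spec <- if (t$kind == "breakpoint_vs_all") taskSpec(t$kind) else
            taskSpec(t$kind, q = t$q)
        tl <- tryCatch(.taskLabels(spec, bundle), error = function(e) NULL)
        nm <- if (is.na(t$q)) t$kind else sprintf("%s_q%s", t$kind,
                                                  format(t$q))
        if (is.null(tl) || length(unique(tl$y)) < 2L) {
            warning(sprintf("task %s skipped: labeling yields a single class",
                            nm))
            next
        }
        res <- runTask(spec, bundle, plan, config)
        if (all(is.na(res$report$roc_auc))) {
            # e.g. a lone positive that stratification keeps in train:
            # no split has a two-class test set
            warning(sprintf("task %s skipped: no split yields a two-class test set",
                            nm))
            next
        }
        results[[nm]] <- res
        tab[[nm]] <- data.frame(
            task = t$kind, q = t$q,
            median_roc_auc = stats::median(res$report$roc_auc, na.rm = TRUE),
            median_lift_recall_p03 = stats::median(res$report$lift_recall_p03,
                                                   na.rm = TRUE))
    }
    list(results = results, table = do.call(rbind, tab))
}

.meanTestScores <- function(res, n) {
    s <- numeric(n); cnt <- numeric(n)
    for (p in res$predictions) {
        s[p$row] <- s[p$row] + p$score
        cnt[p$row] <- cnt[p$row] + 1
    }
    ifelse(cnt > 0, s / cnt, 0)
}

#' Per-group model comparison
#'
#' Fits a hotspot model separately on each feature group at the 99% and
#' 99.5% labeling types, ranks the groups by their scaled mean lift of
#' recall at the 0.03 probability percentile ([scaleGroupScores()]),
#' computes the mean Spearman correlation between every pair of groups'
#' test predictions, and the precision of hotspot calls by cross-group
#' agreement level ([overlapPrecision()]). Groups with zero features are
#' skipped with a warning.
#'
#' @param bundle An analysis bundle.
#' @param groups Feature groups to compare (default: all in the matrix).
#' @param qPair The two labeling types to average over (default
#'   \code{c(99, 99.5)}).
#' @param plan A [splitPlan()].
#' @param config An [rfConfig()].
#' @param top Selection fraction for the overlap analysis (default 0.05).
#' @return List: \code{ranking}, \code{correlation} (matrix), \code{overlap}
#'   (data.frame), \code{results} (per group and labeling type).
#' @export
runGroupComparison <- function(bundle, groups = NULL, qPair = c(99, 99.5),
                               plan = splitPlan(), config = rfConfig(),
                               top = 0.05) {
    if (is.null(groups)) groups <- unique(featureGroups(bundle$fm))
    keep <- vapply(groups, function(g)
        any(featureGroups(bundle$fm) == g), TRUE)
    if (!all(keep)) {
        warning("group(s) with zero features skipped: ",
                paste(groups[!keep], collapse = ", "))
        groups <- groups[keep]
    }
    stopifnot(length(groups) >= 2L)
    results <- list()
    lifts <- matrix(0, nrow = length(groups), ncol = length(qPair),
                    dimnames = list(groups, format(qPair)))
    for (g in groups) for (j in seq_along(qPair)) {
        res <- runTask(taskSpec("hotspot_vs_all", q = qPair[j], groups = g),
                       bundle, plan, config)
        results[[sprintf("%s_q%s", g, format(qPair[j]))]] <- res
        lifts[g, j] <- mean(res$report$lift_recall_p03)
    }
    ranking <- scaleGroupScores(lifts)
    qRef <- qPair[1]
    refNames <- sprintf("%s_q%s", groups, format(qRef))
    corr <- matrix(1, length(groups), length(groups),
                   dimnames = list(groups, groups))
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
        if (i >= j) next
        a <- results[[refNames[i]]]$predictions
        b <- results[[refNames[j]]]$predictions
        rho <- predictionCorrelation(lapply(a, `[[`, "score"),
                                     lapply(b, `[[`, "score"))
        corr[i, j] <- corr[j, i] <- rho
    }
    tl <- .taskLabels(taskSpec("hotspot_vs_all", q = qRef), bundle)
    scoreList <- lapply(refNames, function(nm)
        .meanTestScores(results[[nm]], length(tl$y)))
    names(scoreList) <- groups
    overlap <- overlapPrecision(scoreList, tl$y, top = top)
    list(ranking = ranking, correlation = corr, overlap = overlap,
         lifts = lifts, results = results)
}

#' Density-regression protocol on a coarse grid
#'
#' The comparison protocol against earlier density-regression work:
#' breakpoint densities on (typically 500 kb) windows are regressed on
#' feature densities with the \code{log2(1 + x)} /
#' \code{log2(mean(y) + y)} transforms and assessed by seeded 10-fold
#' cross-validation; folds partition the rows exactly once.
#'
#' @param bundle An analysis bundle built on the coarse grid (e.g.
#'   \code{simConfig(..., windowWidth = 5e5)}).
#' @param nFolds Number of CV folds (default 10).
#' @param config An [rfConfig()].
#' @param seed Fold-assignment seed.
#' @param scales Feature scales used as predictors (default local +
#'   distant coverages).
#' @return Data.frame with \code{fold}, \code{r2}; the mean R-squared is
#'   attached as attribute \code{"meanR2"} and the fold assignment as
#'   \code{"folds"}.
#' @export
runStateOfArtProtocol <- function(bundle, nFolds = 10L, config = rfConfig(),
                                  seed = 1L, scales = c("local", "distant")) {
    tl <- .taskLabels(taskSpec("density_regression"), bundle)
    X <- featureValues(selectFeatures(bundle$fm, scales = scales))
    y <- tl$y
    n <- length(y)
    if (n < nFolds) stop("need at least ", nFolds, " rows")
    set.seed(seed)
    folds <- sample(rep(seq_len(nFolds), length.out = n))
    out <- do.call(rbind, lapply(seq_len(nFolds), function(k) {
        tr <- which(folds != k); te <- which(folds == k)
        cfg <- config; cfg$seed <- config$seed + k
        m <- fitRegressor(X[tr, , drop = FALSE], y[tr], cfg)
        pred <- predict(m, X[te, , drop = FALSE])
        yt <- transformTarget(y[te], m$yMean)
        data.frame(fold = k,
                   r2 = 1 - sum((pred - yt)^2) / sum((yt - mean(yt))^2))
    }))
    attr(out, "meanR2") <- mean(out$r2)
    attr(out, "folds") <- folds
    out
}

#' Paired ablation of feature scales
#'
#' Compares, on identical splits, hotspot models built on local coverages
#' only, local plus distant coverages, binary flags only, and binary flags
#' plus maxima indicators — the design that quantifies the contribution of
#' the distant (1 Mb) landscape and the information lost by binarization.
#' All arms share the same split indices, so per-split differences are
#' paired.
#'
#' @param bundle An analysis bundle (feature matrix must carry all scales).
#' @param q Labeling threshold (default 99).
#' @param plan A [splitPlan()].
#' @param config An [rfConfig()].
#' @return List of [runTask()] results named \code{local},
#'   \code{local_distant}, \code{binary}, \code{binary_maxima}, plus
#'   \code{deltas}: per-split paired ROC AUC differences.
#' @export
runDistantAblation <- function(bundle, q = 99, plan = splitPlan(),
                               config = rfConfig()) {
    arms <- list(local = "local",
                 local_distant = c("local", "distant"),
                 binary = "flag",
                 binary_maxima = c("flag", "maxima"))
    tl <- .taskLabels(taskSpec("hotspot_vs_all", q = q), bundle)
    splits <- makeSplits(bundle$grid, tl$y, plan, rows = tl$rows)
    out <- lapply(arms, function(sc)
        runTask(taskSpec("hotspot_vs_all", q = q, scales = sc), bundle,
                plan, config, splits = splits))
    out$deltas <- data.frame(
        split = out$local$report$split,
        distant_gain = out$local_distant$report$roc_auc -
            out$local$report$roc_auc,
        binary_drop = out$local$report$roc_auc - out$binary$report$roc_auc,
        maxima_gain = out$binary_maxima$report$roc_auc -
            out$binary$report$roc_auc)
    out
}

#' Write a per-split metric report and its aggregate as TSV
#'
#' @param result A [runTask()] result (or any list with \code{report}).
#' @param prefix Output path prefix; writes \code{<prefix>_splits.tsv} and
#'   \code{<prefix>_aggregate.tsv}.
#' @return Character vector of the two paths, invisibly.
#' @export
writeMetricReport <- function(result, prefix) {
    p1 <- paste0(prefix, "_splits.tsv")
    p2 <- paste0(prefix, "_aggregate.tsv")
    utils::write.table(result$report, p1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(aggregateMetrics(result$report[,
                           setdiff(colnames(result$report), "split"),
                           drop = FALSE]),
                       p2, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(p1, p2))
}
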