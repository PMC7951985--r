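#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData
NULL

featureGroupVocabulary <- function() {
    c("non-B DNA", "TF", "HM", "methylation", "HDNase", "TAD",
      "genomic regions")
}

#' Construct a feature track
#'
#' A feature track is a named interval set (e.g. G-quadruplex annotations, a
#' TF's ChIP-seq peaks, a histone-mark domain call set) assigned to one of
#' the seven fixed feature groups.
#'
#' @param name Unique feature name.
#' @param group Group label, one of \code{"non-B DNA"}, \code{"TF"},
#'   \code{"HM"}, \code{"methylation"}, \code{"HDNase"}, \code{"TAD"},
#'   \code{"genomic regions"}.
#' @param intervals A \code{GRanges} of the feature's intervals.
#' @return A \code{FeatureTrack} (list with class attribute).
#' @export
featureTrack <- function(name, group, intervals) {
    group <- match.arg(group, featureGroupVocabulary())
    stopifnot(is.character(name), length(name) == 1L, is(intervals, "GRanges"))
    structure(list(name = name, group = group, intervals = intervals),
              class = "FeatureTrack")
}

#' @export
print.FeatureTrack <- function(x, ...) {
    cat(sprintf("FeatureTrack '%s' [%s]: %d interval(s)\n",
                x$name, x$group, length(x$intervals)))
    invisible(x)
}

.coverageFraction <- function(intervals, bins) {
    merged <- mergeIntervals(intervals)
    covered <- numeric(length(bins))
    hits <- GenomicRanges::findOverlaps(bins, merged, ignore.strand = TRUE)
    if (length(hits)) {
        q <- S4Vectors::queryHits(hits)
        ov <- width(IRanges::pintersect(granges(bins)[q],
                                        granges(merged)[S4Vectors::subjectHits(hits)]))
        covered <- covered + as.numeric(tapply(ov, factor(q, levels = seq_along(bins)),
                                               sum, default = 0))
        covered[is.na(covered)] <- 0
    }
    covered / width(bins)
}

#' Local window coverage of a feature
#'
#' The fraction of each retained window's bases covered by the (merged)
#' feature intervals — overlapping intervals are counted once.
#'
#' @param track A [featureTrack()] or a bare \code{GRanges}.
#' @param grid A [WindowGrid-class].
#' @return Numeric vector in \[0, 1\] aligned to [retainedWindows()].
#' @export
windowCoverage <- function(track, grid) {
    intervals <- if (inherits(track, "FeatureTrack")) track$intervals else track
    win <- retainedWindows(grid)
    if (length(intervals) == 0L)
        return(numeric(length(win)))
    .coverageFraction(intervals, win)
}

#' Distant (1 Mb block) coverage of a feature
#'
#' The genome is tiled by \code{span}-sized blocks aligned to the chromosome
#' start; every window receives the coverage fraction of its containing
#' block. A trailing partial block uses its actual length as denominator.
#' These are the "upper_" distant features that summarize the wider genomic
#' landscape around each window.
#'
#' @param track A [featureTrack()] or bare \code{GRanges}.
#' @param grid A [WindowGrid-class].
#' @param span Block size in bp (default 1 Mb); must be a positive multiple
#'   of the window width.
#' @return Numeric vector in \[0, 1\] aligned to [retainedWindows()].
#' @export
distantCoverage <- function(track, grid, span = 1000000L) {
    intervals <- if (inherits(track, "FeatureTrack")) track$intervals else track
    w <- windowWidth(grid)
    span <- as.integer(span)
    if (span < w)
        stop("span must be at least the window width")
    if (span %% w != 0L)
        stop("span must be a multiple of the window width")
    win <- retainedWindows(grid)
    sl <- seqlengths(win)
    if (any(is.na(sl)))
        stop("grid windows must carry chromosome lengths")
    blocks <- GenomicRanges::tileGenome(sl, tilewidth = span,
                                        cut.last.tile.in.chrom = TRUE)
    frac <- if (length(intervals) == 0L) numeric(length(blocks))
            else .coverageFraction(intervals, blocks)
    hit <- GenomicRanges::findOverlaps(win, blocks, select = "first",
                                       ignore.strand = TRUE)
    frac[hit]
}

#' Binary presence flags
#'
#' @param values Numeric coverage vector.
#' @return Integer vector: 1 where coverage is greater than 0, else 0.
#' @export
binaryFlags <- function(values) as.integer(values > 0)

.neighborStats <- function(values, k) {
    # For each position: max over the k preceding and k following values
    # (fewer near edges); NA-free. Returns list(max, hasNeighbors).
    n <- length(values)
    m <- numeric(n)
    has <- logical(n)
    for (i in seq_len(n)) {
        lo <- max(1L, i - k); hi <- min(n, i + k)
        nb <- c(if (lo < i) values[lo:(i - 1L)],
                if (hi > i) values[(i + 1L):hi])
        has[i] <- length(nb) > 0L
        m[i] <- if (length(nb)) max(nb) else 0
    }
    list(max = m, has = has)
}

#' Local-maximum and percentile-exceedance indicators
#'
#' Derives, from one feature column aligned to the retained windows in
#' coordinate order: binary indicators of the value strictly exceeding the
#' 90/95/99th percentiles of the feature's own distribution; binary
#' indicators of the value strictly exceeding all of the k preceding and k
#' following retained windows on the same chromosome (k = 1, 5, 10; fewer
#' neighbors near chromosome edges are compared as available, and a window
#' with no neighbors gets 0); and the relative difference
#' \code{(x - m) / (m + eps)} with \code{m} the maximum over the
#' 10-per-side neighborhood.
#'
#' @param values Numeric vector aligned to [retainedWindows()].
#' @param grid The [WindowGrid-class] the values are aligned to.
#' @param percentiles Percentile thresholds (default \code{c(90, 95, 99)}).
#' @param neighborhood Neighbor window counts (default \code{c(1, 5, 10)}).
#' @param eps Stabilizer for the relative difference (default \code{1e-9}).
#' @return A numeric matrix with one column per indicator, suffixed
#'   \code{pctl<q>}, \code{nbrmax<k>}, \code{reldiff10}.
#' @export
maximaIndicators <- function(values, grid, percentiles = c(90, 95, 99),
                             neighborhood = c(1L, 5L, 10L), eps = 1e-9) {
    win <- retainedWindows(grid)
    stopifnot(length(values) == length(win))
    chr <- as.character(seqnames(win))
    out <- matrix(0, nrow = length(values),
                  ncol = length(percentiles) + length(neighborhood) + 1L)
    cn <- c(sprintf("pctl%s", format(percentiles)),
            sprintf("nbrmax%d", neighborhood), "reldiff10")
    colnames(out) <- cn
    for (j in seq_along(percentiles)) {
        thr <- stats::quantile(values, percentiles[j] / 100, type = 7,
                               names = FALSE)
        out[, j] <- as.numeric(values > thr)
    }
    relK <- max(neighborhood)
    for (ch in unique(chr)) {
        idx <- which(chr == ch)
        v <- values[idx]
        for (j in seq_along(neighborhood)) {
            ns <- .neighborStats(v, neighborhood[j])
            out[idx, length(percentiles) + j] <-
                as.numeric(ns$has & v > ns$max)
        }
        ns <- .neighborStats(v, relK)
        out[idx, ncol(out)] <- (v - ns$max) / (ns$max + eps)
    }
    out
}

#' Assemble the windows-by-features matrix
#'
#' Builds the full engineered feature matrix over the retained windows:
#' local 100 kb coverage per track, distant 1 Mb block coverage (prefixed
#' \code{upper_}), binary presence flags (prefixed \code{flag_}), and the
#' seven local-maximum/percentile indicator columns per feature. Columns are
#' ordered deterministically by (group, feature name, scale). Returned as a
#' \code{RangedSummarizedExperiment} with the retained windows as rows and
#' per-column \code{feature}, \code{group}, \code{scale} annotations.
#'
#' @param tracks List of [featureTrack()]s with unique names.
#' @param grid A [WindowGrid-class].
#' @param includeDistant Add distant (1 Mb) coverage columns.
#' @param includeFlags Add binary flag columns.
#' @param includeMaxima Add the indicator columns.
#' @param span Distant block size in bp (default 1 Mb).
#' @return A \code{RangedSummarizedExperiment}; assay \code{"features"}.
#' @export
assembleFeatureMatrix <- function(tracks, grid, includeDistant = TRUE,
                                  includeFlags = TRUE, includeMaxima = TRUE,
                                  span = 1000000L) {
    stopifnot(length(tracks) >= 1L)
    nm <- vapply(tracks, `[[`, "", "name")
    if (anyDuplicated(nm))
        stop("duplicate feature names: ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
    grp <- vapply(tracks, `[[`, "", "group")
    ord <- order(grp, nm)
    tracks <- tracks[ord]
    nm <- nm[ord]; grp <- grp[ord]
    win <- retainedWindows(grid)
    cols <- list(); meta <- list()
    for (i in seq_along(tracks)) {
        local <- windowCoverage(tracks[[i]], grid)
        cols[[nm[i]]] <- local
        meta[[length(meta) + 1L]] <- c(nm[i], grp[i], "local")
        if (includeDistant) {
            cols[[paste0("upper_", nm[i])]] <-
                distantCoverage(tracks[[i]], grid, span = span)
            meta[[length(meta) + 1L]] <- c(nm[i], grp[i], "distant")
        }
        if (includeFlags) {
            cols[[paste0("flag_", nm[i])]] <- as.numeric(binaryFlags(local))
            meta[[length(meta) + 1L]] <- c(nm[i], grp[i], "flag")
        }
        if (includeMaxima) {
            mx <- maximaIndicators(local, grid)
            for (k in colnames(mx)) {
                cols[[paste0(nm[i], "_", k)]] <- mx[, k]
                meta[[length(meta) + 1L]] <- c(nm[i], grp[i], "maxima")
            }
        }
    }
    m <- do.call(cbind, cols)
    rownames(m) <- as.character(mcols(win)$window_id)
    md <- do.call(rbind, meta)
    cd <- DataFrame(feature = md[, 1], group = md[, 2], scale = md[, 3],
                    row.names = colnames(m))
    SummarizedExperiment(assays = list(features = m), rowRanges = win,
                         colData = cd)
}

#' Feature values of a feature matrix
#' @param fm A feature matrix from [assembleFeatureMatrix()].
#' @return The numeric windows-by-features matrix.
#' @export
featureValues <- function(fm) assay(fm, "features")

#' Group annotation of feature columns
#' @param fm A feature matrix.
#' @return Character vector of group labels, one per column.
#' @export
featureGroups <- function(fm) as.character(colData(fm)$group)

#' Scale annotation of feature columns
#' @param fm A feature matrix.
#' @return Character vector in \{local, distant, flag, maxima\}.
#' @export
featureScales <- function(fm) as.character(colData(fm)$scale)

#' Subset a feature matrix by group, scale or explicit column names
#'
#' @param fm A feature matrix.
#' @param groups Optional group labels to keep.
#' @param scales Optional scale tags to keep.
#' @param features Optional explicit column names to keep.
#' @return The subset feature matrix (columns only; rows untouched).
#' @export
selectFeatures <- function(fm, groups = NULL, scales = NULL, features = NULL) {
    keep <- rep(TRUE, ncol(fm))
    if (!is.null(groups)) keep <- keep & featureGroups(fm) %in% groups
    if (!is.null(scales)) keep <- keep & featureScales(fm) %in% scales
    if (!is.null(features)) keep <- keep & colnames(fm) %in% features
    fm[, keep]
}

#' Write a feature matrix as annotated TSV
#'
#' The header metadata block (lines starting \code{#feature}) records each
#' column's feature name, group and scale; the body is a TSV keyed by
#' window id and coordinates.
#'
#' @param fm A feature matrix.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeFeatureMatrix <- function(fm, path) {
    con <- file(path, "w")
    on.exit(close(con))
    cd <- colData(fm)
    for (i in seq_len(ncol(fm)))
        writeLines(sprintf("#feature\t%s\t%s\t%s\t%s", colnames(fm)[i],
                           cd$feature[i], cd$group[i], cd$scale[i]), con)
    win <- rowRanges(fm)
    df <- data.frame(window_id = mcols(win)$window_id,
                     chrom = as.character(seqnames(win)),
                     start = start(win), end = end(win),
                     as.data.frame(featureValues(fm), check.names = FALSE),
                     check.names = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a feature matrix written by [writeFeatureMatrix()]
#'
#' @param path Path to the annotated TSV.
#' @return A \code{RangedSummarizedExperiment}.
#' @export
readFeatureMatrix <- function(path) {
    lines <- readLines(path)
    metaLines <- grep("^#feature\t", lines, value = TRUE)
    md <- do.call(rbind, strsplit(sub("^#feature\t", "", metaLines), "\t"))
    body <- lines[!startsWith(lines, "#feature")]
    df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                            check.names = FALSE)
    win <- GRanges(df$chrom, IRanges(df$start, df$end),
                   window_id = as.integer(df$window_id), retained = TRUE)
    m <- as.matrix(df[, md[, 1], drop = FALSE])
    rownames(m) <- as.character(df$window_id)
    SummarizedExperiment(assays = list(features = m), rowRanges = win,
                         colData = DataFrame(feature = md[, 2],
                                             group = md[, 3],
                                             scale = md[, 4],
                                             row.names = md[, 1]))
}
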