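#' Default column mapping for ICGC-style breakpoint tables
#'
#' Maps the internal record fields to the column names of an ICGC
#' structural-somatic-mutation export. Override any entry to read other
#' tabular layouts.
#'
#' @return Named character vector with entries \code{chrom}, \code{start},
#'   \code{end}, \code{donor}, \code{cancerType}.
#' @export
icgcColumnMap <- function() {
    c(chrom = "chromosome", start = "chromosome_start",
      end = "chromosome_end", donor = "icgc_donor_id",
      cancerType = "project_code")
}

#' Parse a breakpoint table into records
#'
#' Each record is one breakpoint locus with a small positional uncertainty
#' interval. Tabular input is 1-based inclusive (the ICGC convention) and is
#' taken directly into the \code{GRanges} convention; a single-base breakpoint
#' (start == end) has width 1.
#'
#' @param table A data.frame (e.g. read from a TSV).
#' @param columnMap Named character vector mapping the fields \code{chrom},
#'   \code{start}, \code{end}, \code{donor}, \code{cancerType} to column
#'   names; defaults to [icgcColumnMap()].
#' @param layout Optional \code{Seqinfo}; rows on chromosomes absent from the
#'   layout are dropped with a warning reporting the count.
#' @return A \code{GRanges} with metadata columns \code{donor} and
#'   \code{cancer_type}.
#' @export
parseBreakpoints <- function(table, columnMap = icgcColumnMap(),
                             layout = NULL) {
    required <- c("chrom", "start", "end", "donor", "cancerType")
    if (!all(required %in% names(columnMap)))
        stop("columnMap must name: ", paste(required, collapse = ", "))
    missing <- setdiff(unname(columnMap[required]), colnames(table))
    if (length(missing))
        stop("missing mapped column(s): ", paste(missing, collapse = ", "))
    s <- suppressWarnings(as.numeric(table[[columnMap["start"]]]))
    e <- suppressWarnings(as.numeric(table[[columnMap["end"]]]))
    bad <- which(is.na(s) | is.na(e))
    if (length(bad))
        stop(sprintf("non-numeric coordinate at row %d", bad[1L]))
    chrom <- as.character(table[[columnMap["chrom"]]])
    keep <- rep(TRUE, nrow(table))
    if (!is.null(layout)) {
        keep <- chrom %in% seqnames(layout)
        if (!all(keep))
            warning(sprintf("dropped %d record(s) on chromosomes absent from the layout",
                            sum(!keep)))
    }
    gr <- GRanges(chrom[keep], IRanges(start = s[keep], end = e[keep]),
                  donor = as.character(table[[columnMap["donor"]]])[keep],
                  cancer_type = as.character(table[[columnMap["cancerType"]]])[keep])
    if (!is.null(layout))
        gr <- GRanges(as.character(seqnames(gr)), IRanges(start(gr), end(gr)),
                      seqinfo = layout, donor = gr$donor,
                      cancer_type = gr$cancer_type)
    gr
}

#' Read an ICGC-style breakpoint TSV
#'
#' @param path Path to a tab-separated file with a header row.
#' @inheritParams parseBreakpoints
#' @return A \code{GRanges} of breakpoint records.
#' @export
readBreakpoints <- function(path, columnMap = icgcColumnMap(),
                            layout = NULL) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE)
    parseBreakpoints(tab, columnMap = columnMap, layout = layout)
}

#' Remove breakpoints with high positional uncertainty
#'
#' Records whose uncertainty interval is wider than \code{maxWidth} bases are
#' removed (strict: a width-10 interval is kept, width 11 is removed). Order
#' is preserved; the operation is idempotent.
#'
#' @param records Breakpoint \code{GRanges}.
#' @param maxWidth Maximum tolerated interval width in bp (default 10).
#' @return Filtered \code{GRanges}.
#' @export
filterUncertain <- function(records, maxWidth = 10L) {
    if (maxWidth < 1L)
        stop("maxWidth must be >= 1")
    records[width(records) <= maxWidth]
}

#' Remove breakpoints in low-mappability regions
#'
#' Drops records whose uncertainty interval overlaps any region of a
#' low-mappability track (e.g. Duke 35-mer uniqueness < 0.5, pre-thresholded
#' by the caller into a BED of low-uniqueness regions).
#'
#' @param records Breakpoint \code{GRanges}.
#' @param lowMapRegions \code{GRanges} of low-mappability regions.
#' @return Filtered \code{GRanges}.
#' @export
filterLowMappability <- function(records, lowMapRegions) {
    if (length(lowMapRegions) == 0L)
        return(records)
    records[!IRanges::overlapsAny(records, lowMapRegions,
                                  ignore.strand = TRUE)]
}

#' Per-window breakpoint counts and densities
#'
#' For each retained window and cancer type, the count is the number of
#' records whose uncertainty interval overlaps the window (a record spanning
#' a window boundary counts in both windows), and the density is that count
#' divided by the total number of records on the window's chromosome for
#' that cancer type (counted whether or not they fall in retained windows).
#' A chromosome with zero records yields zero densities.
#'
#' @param records Breakpoint \code{GRanges} (already record-filtered).
#' @param grid A [WindowGrid-class], built and filtered.
#' @return A \code{DataFrame} with columns \code{window_id},
#'   \code{cancer_type}, \code{count}, \code{density}, ordered by cancer type
#'   then window id.
#' @export
breakpointDensity <- function(records, grid) {
    win <- retainedWindows(grid)
    types <- sort(unique(as.character(records$cancer_type)))
    if (length(types) == 0L) types <- character()
    out <- vector("list", length(types))
    winChr <- as.character(seqnames(win))
    for (i in seq_along(types)) {
        rec <- records[records$cancer_type == types[i]]
        cnt <- GenomicRanges::countOverlaps(win, rec, ignore.strand = TRUE)
        chromTotal <- table(factor(as.character(seqnames(rec)),
                                   levels = unique(winChr)))
        denom <- as.numeric(chromTotal[winChr])
        dens <- ifelse(denom > 0, cnt / denom, 0)
        out[[i]] <- DataFrame(window_id = mcols(win)$window_id,
                              cancer_type = types[i],
                              count = as.integer(cnt),
                              density = as.numeric(dens))
    }
    do.call(rbind, out)
}

#' Hotspot labels at one percentile threshold
#'
#' Per cancer type the threshold is the \code{q}-th percentile (linear
#' interpolation between order statistics) of the density values of all
#' retained windows genome-wide, zeros included; a window is a hotspot iff
#' its density strictly exceeds the threshold. If all densities are equal
#' no window is a hotspot.
#'
#' @param densities \code{DataFrame} from [breakpointDensity()].
#' @param q Percentile in (0, 100), e.g. 99, 99.5, 99.9 (or 75/90/95 for the
#'   low-threshold randomness analyses).
#' @return Logical vector aligned to the rows of \code{densities}.
#' @export
labelHotspots <- function(densities, q) {
    if (!is.numeric(q) || q <= 0 || q >= 100)
        stop("q must lie strictly between 0 and 100")
    flag <- logical(nrow(densities))
    for (ct in unique(densities$cancer_type)) {
        idx <- densities$cancer_type == ct
        d <- densities$density[idx]
        thr <- stats::quantile(d, probs = q / 100, type = 7, names = FALSE)
        flag[idx] <- d > thr
    }
    flag
}

#' Breakpoint-presence labels
#'
#' @param densities \code{DataFrame} from [breakpointDensity()].
#' @return Logical vector: \code{TRUE} where the window carries at least one
#'   breakpoint of that cancer type.
#' @export
labelPresence <- function(densities) {
    densities$count > 0L
}

#' Build the full label set
#'
#' Combines densities, the presence flag, and hotspot flags at every labeling
#' threshold into one table. Hotspot flags are nested by construction: a
#' hotspot at a higher percentile is a hotspot at every lower one.
#'
#' @param densities \code{DataFrame} from [breakpointDensity()].
#' @param thresholds Numeric vector of labeling percentiles
#'   (default \code{c(75, 90, 95, 99, 99.5, 99.9)}).
#' @return A \code{DataFrame} with \code{window_id}, \code{cancer_type},
#'   \code{count}, \code{density}, \code{presence} and one
#'   \code{hotspot_q<threshold>} column per threshold.
#' @export
buildLabelSet <- function(densities, thresholds = c(75, 90, 95, 99, 99.5, 99.9)) {
    out <- densities
    out$presence <- labelPresence(densities)
    for (q in thresholds)
        out[[hotspotColumn(q)]] <- labelHotspots(densities, q)
    out
}

#' Export a density or label table as TSV keyed by window id
#'
#' @param x A \code{DataFrame} from [breakpointDensity()] or
#'   [buildLabelSet()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeWindowTable <- function(x, path) {
    utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Column name of a hotspot flag at a given labeling threshold
#' @param q Labeling percentile.
#' @return Character scalar, e.g. \code{"hotspot_q99.5"}.
#' @export
hotspotColumn <- function(q) sprintf("hotspot_q%s", format(q))
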