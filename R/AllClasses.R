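#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqnames seqlevels keepSeqlevels
NULL

#' WindowGrid: the tiled, filtered genome partition
#'
#' A \code{WindowGrid} holds the non-overlapping window tiling of a genome
#' that defines the unit of analysis for breakpoint-density modeling. Windows
#' are fixed-width (default 100 kb) except possibly the last window of each
#' chromosome. Filtering (terminal windows, centromere/telomere/blacklist
#' exclusions, whole chromosomes) flips a retained-mask; window ids and
#' coordinates are never renumbered, so ids are stable across filtering.
#'
#' @slot windows A \code{GRanges} in coordinate order with metadata columns
#'   \code{window_id} (0-based integer, unique, stable) and \code{retained}
#'   (logical mask).
#' @slot width Integer scalar, the nominal window width in bp.
#'
#' @seealso [buildWindows()], [filterWindows()], [retainedWindows()]
#' @export
setClass("WindowGrid",
    representation(windows = "GRanges", width = "integer"))

setValidity("WindowGrid", function(object) {
    msg <- NULL
    w <- object@windows
    mc <- mcols(w)
    if (!all(c("window_id", "retained") %in% colnames(mc)))
        msg <- c(msg, "windows must carry 'window_id' and 'retained' columns")
    else {
        if (anyDuplicated(mc$window_id))
            msg <- c(msg, "window ids must be unique")
        if (!is.logical(mc$retained))
            msg <- c(msg, "'retained' must be logical")
    }
    if (length(object@width) != 1L || is.na(object@width) || object@width < 1L)
        msg <- c(msg, "width must be a positive integer scalar")
    # windows within each chromosome: contiguous, non-overlapping, width w
    # except possibly the last
    for (chr in as.character(unique(seqnames(w)))) {
        ww <- w[seqnames(w) == chr]
        if (length(ww) == 0L) next
        s <- start(ww); e <- end(ww)
        if (is.unsorted(s)) { msg <- c(msg, "windows must be sorted"); break }
        if (length(ww) > 1L && any(s[-1L] != e[-length(e)] + 1L)) {
            msg <- c(msg, sprintf("windows on %s are not contiguous", chr))
            break
        }
        if (any(width(ww)[-length(ww)] != object@width)) {
            msg <- c(msg, sprintf("interior window on %s not of width w", chr))
            break
        }
    }
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "WindowGrid", function(object) {
    n <- length(object@windows)
    k <- sum(mcols(object@windows)$retained)
    cat(sprintf("WindowGrid: %d windows of %d bp on %d chromosome(s); %d retained\n",
        n, object@width, length(unique(as.character(seqnames(object@windows)))), k))
})

#' @describeIn WindowGrid Number of windows (retained or not).
#' @param x A \code{WindowGrid}.
#' @export
setMethod("length", "WindowGrid", function(x) length(x@windows))
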