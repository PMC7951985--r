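#' Construct a genome layout
#'
#' A genome layout is the ordered set of chromosome names and lengths over
#' which windows are laid. Represented as a \code{Seqinfo}, the standard
#' Bioconductor container for this information.
#'
#' @param chromNames Character vector of unique chromosome names.
#' @param chromLengths Integer vector of positive lengths (bp), parallel to
#'   \code{chromNames}; alternatively a named numeric vector as the single
#'   argument.
#' @return A \code{Seqinfo}.
#' @examples
#' genomeLayout(c(chr1 = 250000, chr2 = 100000))
#' @export
genomeLayout <- function(chromNames, chromLengths = NULL) {
    if (is.null(chromLengths)) {
        chromLengths <- unname(chromNames)
        chromNames <- names(chromNames)
    }
    if (length(chromNames) == 0L)
        stop("empty genome layout")
    if (anyDuplicated(chromNames))
        stop("chromosome names must be unique")
    if (any(!is.finite(chromLengths)) || any(chromLengths < 1))
        stop("every chromosome length must be a positive integer")
    Seqinfo(seqnames = as.character(chromNames),
            seqlengths = as.integer(chromLengths))
}

#' Read a chrom.sizes file
#'
#' Two-column whitespace-separated file (chromosome name, length in bp), the
#' UCSC \code{chrom.sizes} convention.
#'
#' @param path Path to the file.
#' @return A \code{Seqinfo} genome layout.
#' @export
readChromSizes <- function(path) {
    df <- utils::read.table(path, header = FALSE, sep = "",
                            col.names = c("chrom", "size"),
                            colClasses = c("character", "numeric"))
    genomeLayout(df$chrom, df$size)
}

#' Tile a genome into non-overlapping windows
#'
#' Splits every chromosome left-to-right from its first base into
#' non-overlapping windows of width \code{w}; a trailing partial window is
#' kept (it is typically removed later by the terminal-window rule of
#' [filterWindows()]). All windows are initially retained and receive unique
#' stable integer ids in coordinate order.
#'
#' @param layout A \code{Seqinfo} genome layout (see [genomeLayout()]).
#' @param w Window width in bp (default 100 kb, the standard analysis scale).
#' @return A [WindowGrid-class].
#' @examples
#' grid <- buildWindows(genomeLayout(c(chr1 = 250000)), w = 100000)
#' retainedWindows(grid)
#' @export
buildWindows <- function(layout, w = 100000L) {
    if (!is(layout, "Seqinfo"))
        layout <- genomeLayout(layout)
    if (length(seqlengths(layout)) == 0L)
        stop("empty genome layout")
    w <- as.integer(w)
    if (is.na(w) || w < 1L)
        stop("window width must be positive")
    if (all(seqlengths(layout) < w))
        stop("window width exceeds every chromosome length")
    tiles <- GenomicRanges::tileGenome(seqlengths(layout), tilewidth = w,
                                       cut.last.tile.in.chrom = TRUE)
    mcols(tiles)$window_id <- seq_along(tiles) - 1L
    mcols(tiles)$retained <- TRUE
    new("WindowGrid", windows = tiles, width = w)
}

#' Canonicalize an interval set
#'
#' Sorts and merges a set of genomic intervals into the canonical disjoint
#' form, so that overlapping regions are never double-counted in coverage.
#' Touching intervals merge. Idempotent; the covered base pairs are conserved.
#'
#' @param x A \code{GRanges} (possibly overlapping, unordered).
#' @return A sorted, pairwise-disjoint \code{GRanges} covering the same bases.
#' @export
mergeIntervals <- function(x) {
    if (!is(x, "GRanges"))
        stop("intervals must be a GRanges")
    if (any(width(x) < 1L))
        stop("interval with start >= end")
    GenomicRanges::reduce(sort(granges(x)))
}

#' Filter the window grid
#'
#' Clears the retained-mask for (a) the first and last window of every
#' chromosome when \code{dropTerminal}, (b) any window sharing at least one
#' base with any exclusion interval (centromeres/telomeres/assembly gaps,
#' blacklist regions), and (c) all windows on excluded chromosomes (e.g. chrY
#' and chrM, which carry too few breakpoints to analyze). Window ids and
#' coordinates are untouched; only the mask changes, so filtering is
#' composable and reversible.
#'
#' @param grid A [WindowGrid-class].
#' @param exclusions A \code{GRanges}, or list of \code{GRanges}, of regions
#'   to exclude. May be empty.
#' @param dropTerminal Drop the first and last window of each chromosome
#'   (default \code{TRUE}).
#' @param excludedChromosomes Character vector of chromosome names whose
#'   windows are all masked.
#' @return The filtered [WindowGrid-class].
#' @export
filterWindows <- function(grid, exclusions = GRanges(),
                          dropTerminal = TRUE,
                          excludedChromosomes = character()) {
    stopifnot(is(grid, "WindowGrid"))
    w <- grid@windows
    keep <- mcols(w)$retained
    if (dropTerminal) {
        chr <- as.character(seqnames(w))
        first <- !duplicated(chr)
        last <- !duplicated(chr, fromLast = TRUE)
        keep <- keep & !first & !last
    }
    if (is(exclusions, "GRanges"))
        exclusions <- list(exclusions)
    for (ex in exclusions) {
        if (length(ex) == 0L) next
        hit <- IRanges::overlapsAny(w, ex, minoverlap = 1L,
                                    ignore.strand = TRUE)
        keep <- keep & !hit
    }
    if (length(excludedChromosomes))
        keep <- keep & !(as.character(seqnames(w)) %in% excludedChromosomes)
    mcols(w)$retained <- keep
    grid@windows <- w
    grid
}

#' Retained windows of a grid
#'
#' @param grid A [WindowGrid-class].
#' @return A \code{GRanges} of the retained windows, in coordinate order,
#'   with their \code{window_id}s.
#' @export
retainedWindows <- function(grid) {
    stopifnot(is(grid, "WindowGrid"))
    grid@windows[mcols(grid@windows)$retained]
}

#' All windows of a grid (retained or not)
#' @param grid A [WindowGrid-class].
#' @return A \code{GRanges} with \code{window_id} and \code{retained} columns.
#' @export
allWindows <- function(grid) {
    stopifnot(is(grid, "WindowGrid"))
    grid@windows
}

#' Window width of a grid
#' @param grid A [WindowGrid-class].
#' @return Integer scalar width in bp.
#' @export
windowWidth <- function(grid) grid@width

#' Export grid windows as BED
#'
#' Writes the windows (all, or retained only) as a BED file with the window
#' id in the name column.
#'
#' @param grid A [WindowGrid-class].
#' @param path Output path.
#' @param retainedOnly Write only retained windows (default \code{TRUE}).
#' @return The path, invisibly.
#' @export
exportWindowsBed <- function(grid, path, retainedOnly = TRUE) {
    w <- if (retainedOnly) retainedWindows(grid) else allWindows(grid)
    names(w) <- as.character(mcols(w)$window_id)
    mcols(w) <- NULL
    rtracklayer::export.bed(w, path)
    invisible(path)
}

#' Read a BED interval track
#'
#' Standard BED3+ (0-based half-open on disk); imported into the 1-based
#' closed \code{GRanges} convention by rtracklayer.
#'
#' @param path Path to a BED file.
#' @param layout Optional \code{Seqinfo}; intervals on chromosomes absent
#'   from the layout are dropped with a warning.
#' @return A \code{GRanges}.
#' @export
readBedTrack <- function(path, layout = NULL) {
    gr <- rtracklayer::import.bed(path)
    strand(gr) <- "*"
    if (!is.null(layout)) {
        keep <- as.character(seqnames(gr)) %in% seqnames(layout)
        if (!all(keep)) {
            warning(sprintf("dropped %d interval(s) on chromosomes absent from the layout",
                            sum(!keep)))
            gr <- gr[keep]
        }
        gr <- GRanges(as.character(seqnames(gr)), IRanges(start(gr), end(gr)),
                      seqinfo = layout)
    }
    gr
}
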