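# Shared fixtures and small oracles used across the suite.

library(GenomicRanges)
library(S4Vectors)

# 0-based half-open interval (BED-style) -> GRanges, for readable test input
gr0 <- function(chrom, start0, end0, ...) {
    GRanges(chrom, IRanges(start = start0 + 1L, end = end0), ...)
}

# per-base boolean-array coverage oracle (exact, for small chromosomes)
perBaseCoverage <- function(intervals, binStart0, binEnd0) {
    covered <- logical(binEnd0 - binStart0)
    for (i in seq_along(intervals)) {
        s0 <- start(intervals)[i] - 1L
        e0 <- end(intervals)[i]
        lo <- max(s0, binStart0); hi <- min(e0, binEnd0)
        if (hi > lo)
            covered[(lo - binStart0 + 1L):(hi - binStart0)] <- TRUE
    }
    mean(covered)
}

# O(n^2) pair-counting ROC AUC oracle
pairRocAUC <- function(y, s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (n in neg)
        tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
    tot / (length(pos) * length(neg))
}

# small fast forest config for tests that only need qualitative behaviour
fastRF <- function(seed = 1L) rfConfig(nTrees = 150L, minNodeSize = 5L,
                                       seed = seed)

tinyLayout <- function() genomeLayout(c(chr1 = 1e6, chr2 = 5e5))

# cached desk-scale bundles (built once per test run)
.bundleCache <- new.env()
cachedBundle <- function(preset, seed = 1L, key = preset, ...) {
    key <- paste(key, seed, sep = "_")
    if (is.null(.bundleCache[[key]]))
        .bundleCache[[key]] <- simulateBundle(simConfig(preset, seed = seed, ...))
    .bundleCache[[key]]
}
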