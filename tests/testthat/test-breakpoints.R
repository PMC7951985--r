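makeBpTable <- function(chrom, start, end, donor = "DO1", type = "BRCA") {
    data.frame(chromosome = chrom, chromosome_start = start,
               chromosome_end = end, icgc_donor_id = donor,
               project_code = type)
}

test_that("parseBreakpoints converts 1-based inclusive input and drops unknown chromosomes", {
    tab <- makeBpTable("chr1", c(10, 100, 200), c(10, 104, 200))
    rec <- parseBreakpoints(tab)
    expect_equal(length(rec), 3L)
    expect_equal(width(rec), c(1L, 5L, 1L))
    # (10,10) 1-based inclusive is the single base 10: half-open [9,10)
    expect_equal(start(rec)[1], 10L)

    tab2 <- rbind(tab, makeBpTable("chrUn_gl000220", 5, 5))
    expect_warning(rec2 <- parseBreakpoints(tab2, layout = tinyLayout()),
                   "dropped 1")
    expect_equal(length(rec2), 3L)

    expect_error(parseBreakpoints(tab[, -1]), "missing mapped column")
    tab3 <- makeBpTable("chr1", c("10", "x"), c("10", "20"))
    expect_error(parseBreakpoints(tab3), "row 2")
})

test_that("filterUncertain removes wide intervals with a strict 10 bp boundary", {
    rec <- parseBreakpoints(makeBpTable("chr1", c(1, 1, 1), c(1, 10, 11)))
    kept <- filterUncertain(rec)
    expect_equal(width(kept), c(1L, 10L))   # width 11 removed, width 10 kept
    expect_identical(filterUncertain(kept), kept)
    expect_error(filterUncertain(rec, maxWidth = 0), ">= 1")
})

test_that("filterLowMappability drops overlapping records only", {
    rec <- parseBreakpoints(makeBpTable("chr1", c(100, 301), c(105, 305)))
    low <- gr0("chr1", 50, 300)
    kept <- filterLowMappability(rec, low)
    expect_equal(length(kept), 1L)
    expect_equal(start(kept), 301L)
    expect_identical(filterLowMappability(rec, GRanges()), rec)
})

test_that("breakpointDensity counts overlaps and normalizes per chromosome and cancer type", {
    lay <- genomeLayout(c(chr1 = 1e6))
    grid <- filterWindows(buildWindows(lay, 1e5), dropTerminal = FALSE)
    # 50 records on chr1, 5 overlap window 1 ([100k,200k))
    pos <- c(rep(150000, 5), rep(450000, 45))
    rec <- parseBreakpoints(makeBpTable("chr1", pos, pos), layout = lay)
    d <- breakpointDensity(rec, grid)
    expect_equal(d$density[d$window_id == 1L], 0.1)
    expect_equal(sum(d$count), 50L)

    # a record spanning the boundary of windows 2 and 3 counts in both
    rec2 <- parseBreakpoints(makeBpTable("chr1", 299998, 300005), layout = lay)
    d2 <- breakpointDensity(rec2, grid)
    expect_equal(d2$count[d2$window_id %in% c(2L, 3L)], c(1L, 1L))

    # brute-force per-window overlap oracle on random records
    set.seed(11)
    s <- sample(1:999000, 200, replace = TRUE)
    recR <- parseBreakpoints(makeBpTable("chr1", s, s + sample(0:9, 200, TRUE)),
                             layout = lay)
    dR <- breakpointDensity(recR, grid)
    win <- retainedWindows(grid)
    oracle <- vapply(seq_along(win), function(i)
        sum(start(recR) <= end(win)[i] & end(recR) >= start(win)[i]), 0L)
    expect_equal(dR$count, oracle)
})

test_that("density handles zero-record chromosomes and excluded-window denominators", {
    lay <- genomeLayout(c(chr1 = 1e6, chr2 = 5e5))
    grid <- filterWindows(buildWindows(lay, 1e5))
    rec <- parseBreakpoints(makeBpTable("chr1", c(50, 150000), c(50, 150000)),
                            layout = lay)
    d <- breakpointDensity(rec, grid)
    expect_true(all(d$density[d$window_id >= 10] == 0))  # chr2 empty
    # denominator counts the record at position 50 (terminal window, masked)
    expect_equal(max(d$density), 1 / 2)
})

test_that("labelHotspots matches a brute-force percentile oracle and is strict", {
    mkDens <- function(dens) DataFrame(window_id = seq_along(dens) - 1L,
                                       cancer_type = "X",
                                       count = as.integer(dens > 0),
                                       density = dens)
    set.seed(3)
    dens <- sample(seq(0.001, 1, length.out = 1000))
    d <- mkDens(dens)
    for (q in c(75, 90, 95, 99, 99.5, 99.9)) {
        hs <- labelHotspots(d, q)
        thr <- quantile(dens, q / 100, type = 7)
        expect_equal(hs, dens > thr)
        n <- length(dens)
        expect_true(sum(hs) %in% c(floor(n * (1 - q / 100)),
                                   ceiling(n * (1 - q / 100))))
    }
    expect_equal(sum(labelHotspots(mkDens(sample(seq_len(200)) / 200), 99.5)), 1L)
    expect_equal(sum(labelHotspots(mkDens(rep(0.5, 100)), 99)), 0L)
    expect_error(labelHotspots(d, 100), "strictly between")
})

test_that("label set has nested hotspot flags and presence implied by hotspot", {
    b <- cachedBundle("local-signal")
    lab <- b$labels
    qs <- c(75, 90, 95, 99, 99.5, 99.9)
    for (i in seq_len(length(qs) - 1)) {
        hi <- lab[[hotspotColumn(qs[i + 1])]]
        lo <- lab[[hotspotColumn(qs[i])]]
        expect_true(all(lo[hi]), label = sprintf("nesting %s in %s",
                                                 qs[i + 1], qs[i]))
    }
    expect_true(all(lab$presence[lab$hotspot_q75]))
    expect_equal(lab$presence, lab$count > 0L)
})
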