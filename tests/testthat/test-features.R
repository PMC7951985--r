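test_that("windowCoverage matches the per-base oracle on crafted and random input", {
    lay <- genomeLayout(c(chr1 = 1e5))
    grid <- filterWindows(buildWindows(lay, 1e5), dropTerminal = FALSE)
    tr <- gr0("chr1", c(0, 25000), c(50000, 75000))
    expect_equal(windowCoverage(tr, grid), 0.75)
    expect_equal(windowCoverage(gr0("chr1", 90000, 99000), grid), 0.09)
    expect_equal(windowCoverage(GRanges(), grid), 0)

    set.seed(21)
    for (rep in 1:20) {
        n <- sample(1:50, 1)
        s <- sample(0:99000, n, replace = TRUE)
        x <- gr0("chr1", s, pmin(s + sample(1:5000, n, TRUE), 1e5))
        expect_equal(windowCoverage(x, grid), perBaseCoverage(x, 0, 1e5))
    }
})

test_that("coverage of a fully-covered and multi-window grid is exact", {
    lay <- genomeLayout(c(chr1 = 3e5))
    grid <- filterWindows(buildWindows(lay, 1e5), dropTerminal = FALSE)
    expect_equal(windowCoverage(gr0("chr1", 0, 3e5), grid), rep(1, 3))
    # interval order never matters
    set.seed(4)
    s <- sample(0:290000, 30); x <- gr0("chr1", s, s + 4000)
    expect_equal(windowCoverage(x, grid),
                 windowCoverage(x[sample(length(x))], grid))
})

test_that("distantCoverage equals the mean of constituent windows over a full block", {
    lay <- genomeLayout(c(chr1 = 1e6))
    grid <- filterWindows(buildWindows(lay, 1e5), dropTerminal = FALSE)
    # windows i covered fraction i/10: intervals [i*100k, i*100k + i*10k)
    iv <- gr0("chr1", (0:9) * 1e5, (0:9) * 1e5 + (1:10) * 1e4)
    local <- windowCoverage(iv, grid)
    expect_equal(local, (1:10) / 10)
    dist <- distantCoverage(iv, grid, span = 1e6)
    expect_equal(dist, rep(mean(local), 10))
    expect_equal(distantCoverage(GRanges(), grid), rep(0, 10))
    expect_error(distantCoverage(iv, grid, span = 5e4), "at least")
    expect_error(distantCoverage(iv, grid, span = 1.5e5), "multiple")
})

test_that("partial terminal block uses its actual length as denominator", {
    lay <- genomeLayout(c(chr1 = 1.3e6))
    grid <- filterWindows(buildWindows(lay, 1e5), dropTerminal = FALSE)
    # terminal block [1Mb, 1.3Mb): 150 kb covered of 300 kb
    iv <- gr0("chr1", 1.0e6, 1.15e6)
    dist <- distantCoverage(iv, grid, span = 1e6)
    win <- retainedWindows(grid)
    inTail <- start(win) > 1e6
    expect_equal(unique(dist[inTail]), 0.5)
    expect_equal(unique(dist[!inTail]), 0)
})

test_that("binaryFlags is a strict positivity indicator", {
    expect_equal(binaryFlags(c(0, 1e-6, 1, 0.3)), c(0L, 1L, 1L, 1L))
})

test_that("maximaIndicators: neighbor-max flags, edges, constants, relative difference", {
    lay <- genomeLayout(c(chr1 = 3e5))
    grid <- filterWindows(buildWindows(lay, 1e5), dropTerminal = FALSE)
    mx <- maximaIndicators(c(1, 5, 3), grid)
    expect_equal(unname(mx[, "nbrmax1"]), c(0, 1, 0))

    mxc <- maximaIndicators(rep(2, 3), grid)
    expect_equal(unname(mxc[, "nbrmax1"]), rep(0, 3))
    expect_equal(unname(mxc[, "nbrmax5"]), rep(0, 3))

    # relative difference: x=2 with neighborhood max 1 -> ~1
    mr <- maximaIndicators(c(1, 2, 1), grid)
    expect_equal(unname(mr[2, "reldiff10"]), (2 - 1) / (1 + 1e-9))

    # percentile flags: strict exceedance of the type-7 percentile
    lay2 <- genomeLayout(c(chr1 = 2e6))
    grid2 <- filterWindows(buildWindows(lay2, 1e5), dropTerminal = FALSE)
    set.seed(9); v <- runif(20)
    mp <- maximaIndicators(v, grid2)
    expect_equal(unname(mp[, "pctl90"]),
                 as.numeric(v > quantile(v, 0.9, type = 7)))
    expect_true(mean(mp[, "pctl90"]) <= 0.1 + 0.05)
})

test_that("neighbor flags do not cross chromosome boundaries", {
    lay <- genomeLayout(c(chr1 = 2e5, chr2 = 2e5))
    grid <- filterWindows(buildWindows(lay, 1e5), dropTerminal = FALSE)
    # chr1: [3, 1]; chr2: [2, 5] -> chr2 window 1 (value 2) beats only its
    # chr2 neighbor? 2 < 5 -> 0; chr1 window 0 (3 > 1) -> 1
    mx <- maximaIndicators(c(3, 1, 2, 5), grid)
    expect_equal(unname(mx[, "nbrmax1"]), c(1, 0, 0, 1))
})

test_that("assembleFeatureMatrix composes scales deterministically", {
    lay <- genomeLayout(c(chr1 = 2e6))
    grid <- filterWindows(buildWindows(lay, 1e5))
    set.seed(14)
    mkTrack <- function(nm, grp) {
        s <- sample(0:1950000, 40)
        featureTrack(nm, grp, gr0("chr1", s, s + sample(1000:20000, 40, TRUE)))
    }
    tracks <- list(mkTrack("g4", "non-B DNA"), mkTrack("ctcf", "TF"))
    fm <- assembleFeatureMatrix(tracks, grid)
    expect_equal(ncol(fm), 2 + 2 + 2 + 14)
    expect_equal(as.integer(table(featureScales(fm))[c("local", "distant", "flag", "maxima")]),
                 c(2L, 2L, 2L, 14L))
    expect_true(all(grepl("^upper_", colnames(fm)[featureScales(fm) == "distant"])))
    expect_false(any(is.na(featureValues(fm))))
    v <- featureValues(fm)
    expect_true(all(v[, featureScales(fm) %in% c("local", "distant")] >= 0 &
                    v[, featureScales(fm) %in% c("local", "distant")] <= 1))

    fmLocal <- assembleFeatureMatrix(tracks, grid, includeDistant = FALSE,
                                     includeFlags = FALSE,
                                     includeMaxima = FALSE)
    expect_equal(ncol(fmLocal), 2L)

    fm2 <- assembleFeatureMatrix(tracks, grid)
    expect_identical(featureValues(fm), featureValues(fm2))

    expect_error(assembleFeatureMatrix(list(mkTrack("x", "TF"),
                                            mkTrack("x", "TF")), grid),
                 "duplicate")
})

test_that("feature matrix round-trips through annotated TSV", {
    b <- cachedBundle("local-signal")
    dir <- withr::local_tempdir()
    p <- file.path(dir, "fm.tsv")
    writeFeatureMatrix(b$fm, p)
    back <- readFeatureMatrix(p)
    expect_equal(featureValues(back), featureValues(b$fm))
    expect_equal(featureGroups(back), featureGroups(b$fm))
    expect_equal(featureScales(back), featureScales(b$fm))
})
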