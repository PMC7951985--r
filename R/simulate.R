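#' Synthetic-bundle configuration
#'
#' Parameters of the synthetic data generator that emulates the real-mode
#' input bundle: a small multi-chromosome genome, BED-like feature tracks
#' with renewal-process interval structure per feature group, and an
#' ICGC-style breakpoint table drawn from a log-linear intensity model
#' \deqn{\lambda_w = \exp(\beta_0 + \beta^T z_w + \gamma^T u_w)\,\varepsilon_w}
#' over windows, where \eqn{z_w} are standardized local (100 kb) coverages,
#' \eqn{u_w} standardized distant (1 Mb) aggregates and
#' \eqn{\varepsilon_w \sim \mathrm{Gamma}(1/d, d)} a mean-one
#' overdispersion term producing the heavy-tailed recurrent-hotspot
#' structure that high-percentile labeling presumes. A fraction \code{rho}
#' of breakpoints is purely random (uniform over retained windows).
#'
#' Presets bundle the study conditions used throughout the test suite:
#' \describe{
#'   \item{local-signal}{default; ~600 windows, 8 features in 3 groups, one
#'     strong local effect, N = 5000, d = 0.5, rho = 0.1.}
#'   \item{distant-signal}{the effect is carried only by the 1 Mb aggregate
#'     of a locally noisy feature (gamma only).}
#'   \item{null}{rho = 1 (pure noise), larger genome (3 x 40 Mb) and
#'     N = 3000 so presence/hotspot labels are well populated.}
#'   \item{mixed}{rho = 0.5, N = 1200: a feature-driven hotspot component on
#'     top of abundant random breakpoints, leaving many windows empty.}
#' }
#'
#' @param preset One of \code{"local-signal"}, \code{"distant-signal"},
#'   \code{"null"}, \code{"mixed"}.
#' @param seed Integer seed.
#' @param ... Overrides for any configuration field (see Details/defaults in
#'   the implementation): \code{chromosomes}, \code{windowWidth},
#'   \code{distantSpan}, \code{groups}, \code{beta0}, \code{beta},
#'   \code{gamma}, \code{overdispersion}, \code{noiseFraction},
#'   \code{nBreakpoints}, \code{nDonors}, \code{widths},
#'   \code{centromereHalfWidth}, \code{cancerType}.
#' @return A list with class \code{"SimConfig"}.
#' @export
simConfig <- function(preset = c("local-signal", "distant-signal", "null",
                                 "mixed"),
                      seed = 1L, ...) {
    preset <- match.arg(preset)
    cfg <- list(
        preset = preset,
        chromosomes = c(chr1 = 2e7, chr2 = 2e7, chr3 = 2e7),
        windowWidth = 1e5,
        distantSpan = 1e6,
        groups = list(
            list(name = "non-B DNA", nFeatures = 3L, meanLength = 250,
                 meanGap = 1000, clustering = 0.8),
            list(name = "TF", nFeatures = 3L, meanLength = 300,
                 meanGap = 2700, clustering = 0.8),
            list(name = "genomic regions", nFeatures = 2L, meanLength = 5000,
                 meanGap = 15000, clustering = 0.5)),
        beta0 = 0,
        beta = c("non-B DNA_1" = 1.5),
        gamma = numeric(),
        overdispersion = 0.5,
        noiseFraction = 0.1,
        nBreakpoints = 5000L,
        nDonors = 50L,
        widths = list(pSmall = 0.92, smallRange = c(1L, 10L),
                      largeRange = c(11L, 60L)),
        centromereHalfWidth = 50000,
        cancerType = "SIM",
        seed = as.integer(seed))
    if (preset == "distant-signal") {
        cfg$beta <- numeric()
        cfg$gamma <- c("non-B DNA_1" = 2.0)
        # sparse intervals make the carrier's 100 kb coverage mostly sampling
        # noise (~25-30% relative), while modest block-level clustering keeps
        # the true signal comparable to that noise; averaging ten windows into
        # the 1 Mb aggregate recovers it, so the effect is learnable at the
        # distant scale but heavily attenuated at the local scale
        cfg$groups[[1]]$meanLength <- 300
        cfg$groups[[1]]$meanGap <- 5700
        cfg$groups[[1]]$clustering <- 0.35
    } else if (preset == "null") {
        # sized for a concentrated null: feature tracks are autocorrelated at
        # the 1 Mb block scale, so the effective sample size is roughly the
        # number of blocks; ~2400 windows (240 blocks) keep the spurious
        # correlation between a fixed label draw and any smooth feature field
        # small enough that the 30-split median ROC AUC concentrates near 0.5
        cfg$chromosomes <- c(chr1 = 8e7, chr2 = 8e7, chr3 = 8e7)
        cfg$beta <- numeric()
        cfg$noiseFraction <- 1
        cfg$nBreakpoints <- 6000L
    } else if (preset == "mixed") {
        # hotspots feature-driven, presence noise-dominated: the carrier
        # group is sparse and strongly clustered, so the signal half of the
        # breakpoints concentrates in the few dozen windows where the carrier
        # is dense while presence elsewhere comes from the uniform noise half
        cfg$groups[[1]]$meanLength <- 2000
        cfg$groups[[1]]$meanGap <- 50000
        cfg$groups[[1]]$clustering <- 1.5
        cfg$beta <- c("non-B DNA_1" = 3.0)
        cfg$noiseFraction <- 0.5
        cfg$nBreakpoints <- 1200L
    }
    override <- list(...)
    for (nm in names(override)) cfg[[nm]] <- override[[nm]]
    stopifnot(cfg$noiseFraction >= 0, cfg$noiseFraction <= 1,
              cfg$nBreakpoints >= 1L)
    structure(cfg, class = "SimConfig")
}

.simFeatureNames <- function(config) {
    unlist(lapply(config$groups, function(g)
        paste0(g$name, "_", seq_len(g$nFeatures))))
}

.simFeatureGroups <- function(config) {
    unlist(lapply(config$groups, function(g)
        rep(g$name, g$nFeatures)))
}

.sampleWidths <- function(n, spec) {
    small <- stats::runif(n) < spec$pSmall
    w <- integer(n)
    w[small] <- sample(seq(spec$smallRange[1], spec$smallRange[2]),
                       sum(small), replace = TRUE)
    w[!small] <- sample(seq(spec$largeRange[1], spec$largeRange[2]),
                        sum(!small), replace = TRUE)
    w
}

.renewalIntervals <- function(chromLen, meanLength, meanGap, clustering,
                              blockSize) {
    # Renewal process per block: gap ~ Exp(block mean gap), length ~
    # Exp(meanLength); clustering modulates the gap mean block-wise with a
    # mean-one lognormal field, inducing spatial autocorrelation in coverage.
    starts <- integer(0); ends <- integer(0)
    blockStarts <- seq(0, chromLen - 1, by = blockSize)
    for (bs in blockStarts) {
        be <- min(bs + blockSize, chromLen)
        mult <- if (clustering > 0)
            exp(clustering * stats::rnorm(1) - clustering^2 / 2) else 1
        gapMean <- meanGap * mult
        k <- ceiling(2 * (be - bs) / (meanLength + gapMean)) + 10L
        gaps <- stats::rexp(k, rate = 1 / gapMean)
        lens <- pmax(1, stats::rexp(k, rate = 1 / meanLength))
        s <- bs + cumsum(gaps + lens) - lens
        e <- pmin(s + lens, be)
        keep <- s < be & e > s
        starts <- c(starts, floor(s[keep]))
        ends <- c(ends, ceiling(e[keep]))
    }
    list(start = starts, end = pmin(ends, chromLen))
}

#' Simulate feature tracks and the genome layout
#'
#' Draws per-feature interval tracks by a block-modulated renewal process
#' (exponential gaps and lengths), producing per-window coverage
#' distributions with nonzero variance and — for positive clustering —
#' spatial autocorrelation, emulating the interval structure of real
#' annotation and peak tracks.
#'
#' @param config A [simConfig()].
#' @return List with \code{layout} (a \code{Seqinfo}) and \code{tracks}
#'   (list of [featureTrack()]).
#' @export
simulateTracks <- function(config) {
    layout <- genomeLayout(config$chromosomes)
    for (g in config$groups)
        if (g$meanLength >= min(config$chromosomes))
            stop("mean interval length must be smaller than every chromosome")
    set.seed(config$seed)
    nms <- .simFeatureNames(config)
    grps <- .simFeatureGroups(config)
    specs <- do.call(rbind, lapply(config$groups, function(g)
        data.frame(meanLength = g$meanLength, meanGap = g$meanGap,
                   clustering = g$clustering)[rep(1, g$nFeatures), ]))
    tracks <- vector("list", length(nms))
    for (i in seq_along(nms)) {
        chrs <- character(0); st <- integer(0); en <- integer(0)
        for (ch in names(config$chromosomes)) {
            iv <- .renewalIntervals(config$chromosomes[[ch]],
                                    specs$meanLength[i], specs$meanGap[i],
                                    specs$clustering[i], config$distantSpan)
            chrs <- c(chrs, rep(ch, length(iv$start)))
            st <- c(st, iv$start); en <- c(en, iv$end)
        }
        gr <- GRanges(chrs, IRanges(start = st + 1L, end = en),
                      seqinfo = layout)
        tracks[[i]] <- featureTrack(nms[i], grps[i], mergeIntervals(gr))
    }
    list(layout = layout, tracks = tracks)
}

.standardize <- function(m) {
    apply(m, 2, function(v) {
        s <- stats::sd(v)
        if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
    })
}

#' Simulate breakpoints from the log-linear intensity model
#'
#' Allocates \code{round(N (1 - rho))} signal breakpoints to retained
#' windows multinomially with probabilities proportional to the window
#' intensities \eqn{\lambda_w}, plus \code{N rho} noise breakpoints uniform
#' over retained windows. Positions are uniform within the window;
#' positional-uncertainty widths are drawn from the configured mixture
#' (which emits some widths above the 10 bp filter cutoff, exercising the
#' record filter); donors are assigned uniformly.
#'
#' @param config A [simConfig()].
#' @param tracks Feature tracks from [simulateTracks()].
#' @param grid The filtered [WindowGrid-class] the tracks are featurized on.
#' @return List with \code{breakpoints} (a \code{GRanges} with \code{donor},
#'   \code{cancer_type} and \code{is_noise} columns; exactly \code{N}
#'   records) and \code{truth} (per-window \code{lambda}, \code{expected}
#'   counts summing to \code{N (1 - rho)}, \code{trueHotspot} flag marking
#'   the top 1\% of \eqn{\lambda}, plus the effect vectors).
#' @export
simulateBreakpoints <- function(config, tracks, grid) {
    win <- retainedWindows(grid)
    nWin <- length(win)
    nms <- vapply(tracks, `[[`, "", "name")
    zl <- .standardize(vapply(tracks, windowCoverage, numeric(nWin),
                              grid = grid))
    zu <- .standardize(vapply(tracks, distantCoverage, numeric(nWin),
                              grid = grid, span = config$distantSpan))
    colnames(zl) <- colnames(zu) <- nms
    eta <- rep(config$beta0, nWin)
    for (f in names(config$beta)) {
        if (!f %in% nms) stop("unknown feature in beta: ", f)
        eta <- eta + config$beta[[f]] * zl[, f]
    }
    for (f in names(config$gamma)) {
        if (!f %in% nms) stop("unknown feature in gamma: ", f)
        eta <- eta + config$gamma[[f]] * zu[, f]
    }
    if (length(config$beta) == 0L && length(config$gamma) == 0L &&
        config$noiseFraction < 1)
        warning("all effects zero with noiseFraction < 1: the signal component is signal-free")
    set.seed(config$seed + 1L)
    d <- config$overdispersion
    eps <- if (d > 0) stats::rgamma(nWin, shape = 1 / d, scale = d) else
        rep(1, nWin)
    eps <- pmax(eps, 1e-12)
    lambda <- exp(eta) * eps
    N <- config$nBreakpoints
    nSignal <- round(N * (1 - config$noiseFraction))
    probs <- lambda / sum(lambda)
    counts <- if (nSignal > 0)
        as.integer(stats::rmultinom(1, nSignal, probs)) else integer(nWin)
    signalWin <- rep(seq_len(nWin), counts)
    noiseWin <- if (N - nSignal > 0)
        sample(nWin, N - nSignal, replace = TRUE) else integer(0)
    allWin <- c(signalWin, noiseWin)
    isNoise <- c(rep(FALSE, length(signalWin)), rep(TRUE, length(noiseWin)))
    widths <- .sampleWidths(N, config$widths)
    ws <- start(win)[allWin]; we <- end(win)[allWin]
    pos <- ws + floor(stats::runif(N) * (we - ws + 1))
    sl <- seqlengths(win)[as.character(seqnames(win))[allWin]]
    bpEnd <- pmin(pos + widths - 1L, sl)
    donors <- sprintf("DO%04d", sample(config$nDonors, N, replace = TRUE))
    gr <- GRanges(as.character(seqnames(win))[allWin],
                  IRanges(start = pos, end = bpEnd),
                  seqinfo = GenomeInfoDb::seqinfo(win),
                  donor = donors, cancer_type = config$cancerType,
                  is_noise = isNoise)
    # true hotspots: top 1% of expected breakpoint density, i.e. lambda
    # normalized by its chromosome's lambda total — the same normalization
    # the density labeler applies, so the truth is recoverable from labels
    chr <- as.character(seqnames(win))
    chromLambda <- tapply(lambda, chr, sum)
    expDensity <- lambda / as.numeric(chromLambda[chr])
    k <- ceiling(0.01 * nWin)
    hot <- logical(nWin)
    hot[order(-expDensity, mcols(win)$window_id)[seq_len(k)]] <- TRUE
    truth <- list(
        window_id = mcols(win)$window_id,
        lambda = lambda,
        expectedDensity = expDensity,
        expected = nSignal * probs,
        trueHotspot = hot,
        beta = config$beta, gamma = config$gamma,
        nSignal = nSignal, nNoise = N - nSignal)
    list(breakpoints = gr, truth = truth)
}

#' Generate a complete synthetic analysis bundle
#'
#' Runs the full generator: layout, window grid (filtered for terminal
#' windows and synthetic centromere stubs), feature tracks, feature matrix
#' (all scales), breakpoints, and the derived density/label tables — the
#' same objects the real-mode pipeline produces from ICGC/ENCODE-style
#' files.
#'
#' @param config A [simConfig()].
#' @return A bundle list: \code{config}, \code{layout}, \code{grid},
#'   \code{exclusions}, \code{tracks}, \code{fm}, \code{breakpoints} (raw),
#'   \code{records} (after the uncertainty filter), \code{densities},
#'   \code{labels}, \code{truth}.
#' @export
simulateBundle <- function(config = simConfig()) {
    tr <- simulateTracks(config)
    grid <- buildWindows(tr$layout, w = config$windowWidth)
    mids <- floor(config$chromosomes / 2)
    excl <- GRanges(names(config$chromosomes),
                    IRanges(start = mids - config$centromereHalfWidth + 1,
                            end = mids + config$centromereHalfWidth),
                    seqinfo = tr$layout)
    grid <- filterWindows(grid, excl, dropTerminal = TRUE)
    fm <- assembleFeatureMatrix(tr$tracks, grid, span = config$distantSpan)
    sim <- simulateBreakpoints(config, tr$tracks, grid)
    records <- filterUncertain(sim$breakpoints)
    densities <- breakpointDensity(records, grid)
    labels <- buildLabelSet(densities)
    list(config = config, layout = tr$layout, grid = grid,
         exclusions = excl, tracks = tr$tracks, fm = fm,
         breakpoints = sim$breakpoints, records = records,
         densities = densities, labels = labels, truth = sim$truth)
}

.configForJson <- function(config) {
    cfg <- unclass(config)
    cfg$chromosomes <- as.list(cfg$chromosomes)
    cfg$beta <- as.list(cfg$beta)
    cfg$gamma <- as.list(cfg$gamma)
    cfg
}

#' Hash of a generator configuration
#'
#' MD5 of the canonical JSON serialization of the config; changes iff any
#' configuration field changes.
#'
#' @param config A [simConfig()].
#' @return Character MD5 hash.
#' @export
configHash <- function(config) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp))
    writeLines(jsonlite::toJSON(.configForJson(config), auto_unbox = TRUE,
                                digits = NA), tmp)
    unname(tools::md5sum(tmp))
}

#' Write a bundle to disk in real-mode formats
#'
#' Writes exactly the file formats the real-mode readers consume:
#' \code{chrom.sizes}, one BED per feature track plus a track manifest TSV,
#' an ICGC-style breakpoint TSV (1-based inclusive coordinates), the
#' synthetic centromere exclusion BED, the ground-truth JSON, and a run
#' manifest with the full config, seed and config hash.
#'
#' @param bundle A bundle from [simulateBundle()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
writeBundle <- function(bundle, dir) {
    ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
    if (!ok || file.access(dir, 2) != 0)
        stop("cannot write to directory: ", dir)
    dir.create(file.path(dir, "tracks"), showWarnings = FALSE)
    lay <- bundle$layout
    utils::write.table(
        data.frame(chrom = seqnames(lay), size = seqlengths(lay)),
        file.path(dir, "chrom.sizes"), sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    manifestTracks <- do.call(rbind, lapply(bundle$tracks, function(t) {
        fn <- file.path("tracks", paste0(gsub("[^A-Za-z0-9._-]", "_", t$name),
                                         ".bed"))
        gr <- t$intervals
        mcols(gr) <- NULL
        rtracklayer::export.bed(gr, file.path(dir, fn))
        data.frame(name = t$name, group = t$group, path = fn)
    }))
    utils::write.table(manifestTracks, file.path(dir, "tracks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    bp <- bundle$breakpoints
    utils::write.table(
        data.frame(icgc_donor_id = bp$donor, project_code = bp$cancer_type,
                   chromosome = as.character(seqnames(bp)),
                   chromosome_start = start(bp), chromosome_end = end(bp)),
        file.path(dir, "breakpoints.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    ex <- bundle$exclusions
    mcols(ex) <- NULL
    rtracklayer::export.bed(ex, file.path(dir, "exclusions.bed"))
    jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- list(config = .configForJson(bundle$config),
                     configHash = configHash(bundle$config),
                     files = c("chrom.sizes", "tracks.tsv",
                               "breakpoints.tsv", "exclusions.bed",
                               "truth.json", manifestTracks$path))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(manifest)
}

#' Read a bundle written by [writeBundle()]
#'
#' Reconstructs the full in-memory bundle through the real-mode readers and
#' recomputes grid, feature matrix, densities and labels, so a fresh process
#' reproduces all downstream results.
#'
#' @param dir Bundle directory.
#' @return A bundle list of the same shape as [simulateBundle()] returns.
#' @export
readBundle <- function(dir) {
    manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
    cfg <- manifest$config
    layout <- readChromSizes(file.path(dir, "chrom.sizes"))
    trackTab <- utils::read.table(file.path(dir, "tracks.tsv"), header = TRUE,
                                  sep = "\t", stringsAsFactors = FALSE)
    tracks <- lapply(seq_len(nrow(trackTab)), function(i)
        featureTrack(trackTab$name[i], trackTab$group[i],
                     readBedTrack(file.path(dir, trackTab$path[i]), layout)))
    excl <- readBedTrack(file.path(dir, "exclusions.bed"), layout)
    grid <- buildWindows(layout, w = as.integer(cfg$windowWidth))
    grid <- filterWindows(grid, excl, dropTerminal = TRUE)
    fm <- assembleFeatureMatrix(tracks, grid,
                                span = as.integer(cfg$distantSpan))
    bps <- readBreakpoints(file.path(dir, "breakpoints.tsv"), layout = layout)
    records <- filterUncertain(bps)
    densities <- breakpointDensity(records, grid)
    labels <- buildLabelSet(densities)
    truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                                 simplifyVector = TRUE)
    list(config = cfg, layout = layout, grid = grid, exclusions = excl,
         tracks = tracks, fm = fm, breakpoints = bps, records = records,
         densities = densities, labels = labels, truth = truth)
}
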