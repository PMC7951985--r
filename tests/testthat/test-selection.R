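# logistic generator with planted informative features, used for Boruta checks
borutaData <- function(n = 250, pSignal = 3, pNoise = 8, beta = 2, seed = 1) {
    set.seed(seed)
    X <- matrix(runif(n * (pSignal + pNoise)), n,
                dimnames = list(NULL, c(paste0("sig", seq_len(pSignal)),
                                        paste0("noise", seq_len(pNoise)))))
    eta <- -beta * pSignal / 2 + X[, seq_len(pSignal), drop = FALSE] %*%
        rep(beta, pSignal)
    y <- rbinom(n, 1, plogis(eta))
    list(X = X, y = y)
}

test_that("boruta confirms planted features, rejects noise, and is deterministic", {
    d <- borutaData(n = 300, pSignal = 3, pNoise = 8, beta = 3, seed = 2)
    res <- boruta(d$X, d$y, fastRF(), maxIter = 25, seed = 10)
    expect_setequal(res$status[grepl("^sig", res$feature)],
                    "confirmed")
    expect_false(any(res$status[grepl("^noise", res$feature)] == "confirmed"))
    expect_true(all(res$hits <= res$iterations))
    expect_identical(res, boruta(d$X, d$y, fastRF(), maxIter = 25, seed = 10))
    expect_error(boruta(d$X, d$y, fastRF(), maxIter = 0), "maxIter")
    expect_error(boruta(d$X[, 1, drop = FALSE], d$y), "at least 2")
})

test_that("boruta confirms nothing when the target is permuted", {
    d <- borutaData(n = 300, seed = 3)
    set.seed(99)
    yPerm <- sample(d$y)
    res <- boruta(d$X, yPerm, fastRF(), maxIter = 20, seed = 4)
    expect_equal(sum(res$status == "confirmed"), 0)
})

test_that("boruta keeps duplicated informative features (no exclusivity)", {
    d <- borutaData(n = 300, pSignal = 2, pNoise = 5, beta = 3, seed = 5)
    X2 <- cbind(d$X, sig1copy = d$X[, "sig1"])
    res <- boruta(X2, d$y, fastRF(), maxIter = 25, seed = 6)
    expect_false(res$status[res$feature == "sig1"] == "rejected")
    expect_false(res$status[res$feature == "sig1copy"] == "rejected")
})

test_that("forwardSelect adds the single sufficient candidate and stops", {
    set.seed(12)
    n <- 400
    X <- cbind(base1 = runif(n), good = runif(n), junk1 = runif(n),
               junk2 = runif(n))
    y <- as.integer(X[, "good"] > 0.5)
    splits <- lapply(1:4, function(r) {
        set.seed(r); te <- sample(n, 120)
        list(train = setdiff(seq_len(n), te), test = te)
    })
    added <- forwardSelect(X, y, base = "base1",
                           candidates = c("good", "junk1", "junk2"),
                           splits = splits, config = fastRF(),
                           tolerance = 0.01)
    expect_equal(added, "good", ignore_attr = TRUE)

    none <- forwardSelect(X, y, base = c("base1", "good"),
                          candidates = c("junk1", "junk2"),
                          splits = splits, config = fastRF(),
                          tolerance = 0.01)
    expect_length(none, 0)

    inf <- forwardSelect(X, y, base = "base1",
                         candidates = c("good", "junk1"),
                         splits = splits, config = fastRF(), tolerance = Inf)
    expect_length(inf, 0)
    expect_error(forwardSelect(X, y, base = "good", candidates = "good",
                               splits = splits), "disjoint")
    expect_length(forwardSelect(X, y, "base1", character(), splits), 0)
})

test_that("scaleGroupScores scales per labeling type, averages, ranks", {
    lifts <- rbind(A = c(4, 3), B = c(2, 3))
    colnames(lifts) <- c("99", "99.5")
    r <- scaleGroupScores(lifts)
    expect_equal(r$score[r$group == "A"], 1)
    expect_equal(r$score[r$group == "B"], 0.75)
    expect_equal(r$rank[r$group == "A"], 1L)

    single <- scaleGroupScores(rbind(A = c(2, 5)))
    expect_equal(single$score, 1)

    withZero <- scaleGroupScores(rbind(A = c(4, 3), Z = c(0, 0)))
    expect_equal(withZero$score[withZero$group == "Z"], 0)
    expect_equal(max(withZero$rank[withZero$group == "Z"]), 2L)

    allZero <- scaleGroupScores(rbind(A = c(0, 0), B = c(0, 0)))
    expect_equal(allZero$score, c(0, 0))

    # invariant under positive rescaling within a labeling type
    r2 <- scaleGroupScores(lifts * rep(c(7, 0.3), each = 2))
    expect_equal(r2$score, r$score)
})

test_that("importanceFrequency applies the at-least-threshold-fraction rule", {
    mk <- function(confirmed) data.frame(
        feature = c("a", "b"),
        status = ifelse(c("a", "b") %in% confirmed, "confirmed", "rejected"),
        hits = 0L, iterations = 1L)
    results <- c(replicate(300, mk("a"), simplify = FALSE),
                 replicate(299, mk(character()), simplify = FALSE),
                 replicate(2401, mk(character()), simplify = FALSE))
    r <- importanceFrequency(results, threshold = 0.1)
    expect_equal(r$feature, "a")          # 300/3000 = exactly the boundary
    expect_equal(r$nConfirmed, 300L)

    results299 <- c(replicate(299, mk("b"), simplify = FALSE),
                    replicate(2701, mk(character()), simplify = FALSE))
    expect_equal(nrow(importanceFrequency(results299, 0.1)), 0L)
    expect_equal(nrow(importanceFrequency(list(), 0.1)), 0L)
})

test_that("strengthening a planted effect never lowers its confirmation frequency", {
    cfg <- rfConfig(nTrees = 120L, minNodeSize = 5L)
    freq <- vapply(c(0, 1.5, 3), function(beta) {
        conf <- 0L
        for (s in 1:10) {
            set.seed(5000 + s)
            n <- 200
            X <- matrix(runif(n * 6), n,
                        dimnames = list(NULL, c("planted", paste0("n", 1:5))))
            y <- rbinom(n, 1, plogis(beta * (X[, "planted"] - 0.5)))
            if (length(unique(y)) < 2) next
            res <- boruta(X, y, cfg, maxIter = 15, seed = s)
            conf <- conf +
                as.integer(res$status[res$feature == "planted"] == "confirmed")
        }
        conf / 10
    }, 0)
    expect_true(all(diff(freq) >= 0))
    expect_gt(freq[3], freq[1])
})
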