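test_that("selectTop picks exactly ceiling(p*n) rows with deterministic ties", {
    set.seed(1)
    s <- sample(seq(0.001, 1, length.out = 100))
    expect_equal(sort(s[selectTop(s, 0.03)], decreasing = TRUE),
                 sort(s, decreasing = TRUE)[1:3])
    expect_length(selectTop(runif(25), 0.1), 3L)  # ceiling(2.5)
    expect_equal(selectTop(rep(0.7, 10), 0.3), 1:3)
    expect_error(selectTop(numeric(0), 0.1), "empty")
    expect_error(selectTop(s, 1.2))
})

test_that("lift closed forms: perfect ranking, no positives in top, random baseline", {
    n <- 1000
    y <- c(rep(1, 10), rep(0, n - 10))          # prevalence 0.01
    sPerfect <- seq(1, 0, length.out = n)
    expect_equal(liftOfRecall(y, sPerfect, 0.03), 1 / 0.03)
    expect_equal(liftOfRecall(y, sPerfect, 0.03), min(1 / 0.01, 1 / 0.03),
                 tolerance = 1e-12)
    expect_equal(liftOfPrecision(y, sPerfect, 0.01), 1 / 0.01)

    sWorst <- seq(0, 1, length.out = n)
    expect_equal(liftOfRecall(y, sWorst, 0.03), 0)
    expect_equal(liftOfPrecision(y, sWorst, 0.03), 0)

    set.seed(5)
    lifts <- replicate(300, liftOfRecall(y, runif(n), 0.1))
    expect_equal(mean(lifts), 1, tolerance = 0.15)
    expect_error(liftOfRecall(rep(0, 10), runif(10), 0.1), "no positives")
})

test_that("rocAUC equals the O(n^2) pair oracle including ties", {
    expect_equal(rocAUC(c(0, 1, 0, 1), c(0.1, 0.9, 0.8, 0.7)), 0.75)
    expect_equal(rocAUC(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
    expect_equal(rocAUC(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
    set.seed(8)
    for (rep in 1:20) {
        n <- sample(10:200, 1)
        y <- rbinom(n, 1, 0.3); if (sum(y) %in% c(0, n)) next
        s <- round(runif(n), 2)   # coarse scores force ties
        expect_equal(rocAUC(y, s), pairRocAUC(y, s))
    }
    expect_error(rocAUC(rep(1, 5), runif(5)), "both classes")
})

test_that("rocAUC agrees with an independent library implementation", {
    skip_if_not_installed("pROC")
    set.seed(12)
    y <- rbinom(400, 1, 0.2); s <- runif(400)
    expect_equal(rocAUC(y, s),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
})

test_that("prAUC: perfect ranking, random scorer near prevalence", {
    y <- c(rep(1, 5), rep(0, 95))
    expect_equal(prAUC(y, seq(1, 0, length.out = 100)), 1)
    set.seed(31)
    n <- 10000; y2 <- rbinom(n, 1, 0.1)
    expect_equal(prAUC(y2, runif(n)), mean(y2), tolerance = 0.05)
})

test_that("metrics are invariant to strictly monotone score transforms", {
    set.seed(17)
    y <- rbinom(300, 1, 0.1); s <- runif(300)
    for (f in list(function(x) x^3, function(x) exp(2 * x),
                   function(x) log(x + 1))) {
        expect_equal(rocAUC(y, s), rocAUC(y, f(s)))
        expect_equal(prAUC(y, s), prAUC(y, f(s)))
        expect_equal(liftOfRecall(y, s, 0.05), liftOfRecall(y, f(s), 0.05))
    }
})

test_that("mcfaddenR2 formula, boundaries and errors", {
    expect_equal(mcfaddenR2(-100, -100), 0)
    expect_equal(mcfaddenR2(-50, -100), 0.5)
    expect_equal(mcfaddenR2(-1e-9, -100), 1, tolerance = 1e-9)
    expect_error(mcfaddenR2(5, -10))
    expect_error(mcfaddenR2(-5, 1))
})

test_that("predictionCorrelation averages Spearman rho and skips constant splits", {
    a <- list(c(1, 2, 3, 4), c(4, 3, 2, 1))
    expect_equal(predictionCorrelation(a, a), 1)
    rev <- lapply(a, function(x) -x)
    expect_equal(predictionCorrelation(a, rev), -1)
    set.seed(23)
    x <- replicate(5, runif(1000), simplify = FALSE)
    z <- replicate(5, runif(1000), simplify = FALSE)
    expect_lt(abs(predictionCorrelation(x, z)), 0.1)
    withConst <- c(a, list(rep(1, 4)))
    other <- c(a, list(c(1, 2, 3, 4)))
    expect_warning(r <- predictionCorrelation(withConst, other), "constant")
    expect_equal(r, 1)
})

test_that("overlapPrecision assigns agreement levels and per-level precision", {
    # 3 groups over 100 windows with controlled overlap of top-5% picks
    n <- 100
    mkScores <- function(top) { s <- runif(n, 0, 0.5); s[top] <- 1 - top / 1000; s }
    set.seed(2)
    sl <- list(A = mkScores(1:5), B = mkScores(3:7), C = mkScores(6:10))
    y <- rep(0, n); y[c(3, 4, 6, 7)] <- 1
    op <- overlapPrecision(sl, y, top = 0.05)
    # windows 3,4,5,6,7 selected by exactly two groups; 3,4,6,7 are true
    expect_equal(op$nSelected[op$agreement == 2], 5)
    expect_equal(op$precision[op$agreement == 2], 4 / 5)

    same <- list(A = sl$A, B = sl$A, C = sl$A)
    opSame <- overlapPrecision(same, y, top = 0.05)
    expect_equal(opSame$nSelected[opSame$agreement == 3], 5)
    expect_equal(sum(opSame$nSelected[opSame$agreement < 3]), 0)

    disj <- list(A = mkScores(1:5), B = mkScores(11:15), C = mkScores(21:25))
    opD <- overlapPrecision(disj, y, top = 0.05)
    expect_equal(opD$nSelected[opD$agreement == 1], 15)
})

test_that("aggregateMetrics reports mean, median and the normal CI of the mean", {
    rep <- data.frame(roc_auc = c(0.6, 0.7, 0.8))
    agg <- aggregateMetrics(rep)
    expect_equal(agg$mean, 0.7)
    expect_equal(agg$median, 0.7)
    se <- sd(rep$roc_auc) / sqrt(3)
    expect_equal(agg$ciLow, 0.7 - 1.96 * se)
    expect_equal(agg$ciHigh, 0.7 + 1.96 * se)
})
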