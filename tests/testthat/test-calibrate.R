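test_that("ROC handles separation, symmetry and degenerate inputs", {
    r <- rocCurve(c(30, 40, 10, 20), c(TRUE, TRUE, FALSE, FALSE))
    expect_equal(rocAuc(r), 1)
    expect_identical(youdenThreshold(r), 25)
    expect_identical(topLeftThreshold(r), 25)

    # identical multisets in both classes: chance performance
    r2 <- rocCurve(c(1, 2, 3, 1, 2, 3), rep(c(TRUE, FALSE), each = 3))
    expect_equal(rocAuc(r2), 0.5)

    # single pos / single neg: midpoint threshold
    r3 <- rocCurve(c(30, 10), c(TRUE, FALSE))
    expect_identical(youdenThreshold(r3), 20)
    expect_identical(topLeftThreshold(r3), 20)

    expect_error(rocCurve(c(1, 2), c(TRUE, TRUE)), "at least one")
})

test_that("trapezoidal AUC equals the normalized rank-sum on tied data", {
    set.seed(31)
    for (i in 1:20) {
        n1 <- sample(3:60, 1); n2 <- sample(3:60, 1)
        sc <- c(sample(1:15, n1, replace = TRUE),
                sample(3:18, n2, replace = TRUE))
        lab <- rep(c(TRUE, FALSE), c(n1, n2))
        u <- suppressWarnings(
            wilcox.test(sc[lab], sc[!lab])$statistic)  # U with ties half
        expect_equal(rocAuc(rocCurve(sc, lab)), unname(u) / (n1 * n2),
                     tolerance = 1e-12)
    }
})

test_that("AUC is invariant under strictly monotone score transforms", {
    set.seed(32)
    sc <- rnorm(80, 20, 10)
    lab <- rep(c(TRUE, FALSE), 40)
    base <- rocAuc(rocCurve(sc, lab))
    for (f in list(function(x) 3 * x + 7, exp, function(x) x^3)) {
        expect_equal(rocAuc(rocCurve(f(sc), lab)), base, tolerance = 1e-12)
    }
})

test_that("agreement with pROC on random data", {
    set.seed(33)
    sc <- round(rnorm(100, 25, 9))
    lab <- rep(c(TRUE, FALSE), 50)
    ours <- rocAuc(rocCurve(sc, lab))
    ref <- as.numeric(pROC::auc(pROC::roc(
        response = lab, predictor = sc, quiet = TRUE,
        direction = "<", levels = c(FALSE, TRUE))))
    expect_equal(ours, ref, tolerance = 1e-12)
    # and the Youden threshold matches pROC's midpoint-based choice
    yj <- pROC::coords(pROC::roc(response = lab, predictor = sc,
                                 quiet = TRUE, direction = "<",
                                 levels = c(FALSE, TRUE)),
                       "best", best.method = "youden",
                       ret = "threshold")[[1]]
    expect_equal(youdenThreshold(rocCurve(sc, lab)), min(yj))
})

test_that("integer scores yield half-integer operating thresholds", {
    set.seed(34)
    sc <- round(c(rnorm(500, 36.10, 9.72), rnorm(500, 19.20, 5.52)))
    lab <- rep(c(TRUE, FALSE), each = 500)
    r <- rocCurve(sc, lab)
    yt <- youdenThreshold(r); tt <- topLeftThreshold(r)
    expect_identical(yt %% 1, 0.5)
    expect_identical(tt %% 1, 0.5)
})

test_that("large-sample Youden threshold approaches the density crossing", {
    cross <- binormalDensityCrossing(36.10, 9.72, 19.20, 5.52)
    set.seed(35)
    sc <- c(rnorm(10000, 36.10, 9.72), rnorm(10000, 19.20, 5.52))
    lab <- rep(c(TRUE, FALSE), each = 10000)
    r <- rocCurve(sc, lab)
    expect_lt(abs(youdenThreshold(r) - cross), 1.5)
    # symmetric-enough classes: both criteria nearly coincide
    expect_lt(abs(topLeftThreshold(r) - youdenThreshold(r)), 1.5)
})

test_that("exact binomial intervals reproduce known closed forms", {
    ci <- clopperPearson(97, 100)
    expect_lt(abs(ci@lower - 91.48), 0.005)
    expect_lt(abs(ci@upper - 99.38), 0.005)
    ci2 <- clopperPearson(100, 100)
    expect_identical(ci2@upper, 100)
    expect_lt(abs(ci2@lower - 96.38), 0.005)
    expect_equal(ci2@lower, 100 * 0.025^(1 / 100), tolerance = 1e-12)
    ci3 <- clopperPearson(22, 22)
    expect_equal(ci3@lower, 100 * 0.025^(1 / 22), tolerance = 1e-12)
    expect_lt(abs(ci3@lower - 84.56), 0.005)
    ci4 <- clopperPearson(0, 1)
    expect_identical(ci4@lower, 0)
    expect_equal(ci4@upper, 97.5, tolerance = 1e-12)
    expect_error(clopperPearson(5, 4), "successes")
    expect_error(clopperPearson(-1, 4), "successes")
})

test_that("exact intervals agree with binom.test everywhere", {
    for (n in c(1, 7, 22, 100)) {
        for (s in unique(c(0, 1, floor(n / 2), n))) {
            ours <- clopperPearson(s, n)
            ref <- binom.test(s, n)$conf.int
            expect_equal(c(ours@lower, ours@upper) / 100, as.numeric(ref),
                         tolerance = 1e-10)
        }
    }
})

test_that("exact interval coverage is at least nominal in simulation", {
    set.seed(36)
    for (p in c(0.1, 0.5, 0.9)) {
        for (n in c(20, 100)) {
            x <- rbinom(2000, n, p)
            lo <- ifelse(x == 0, 0, qbeta(0.025, x, n - x + 1))
            hi <- ifelse(x == n, 1, qbeta(0.975, x + 1, n - x))
            # vectorized oracle above mirrors clopperPearson; spot-check it
            spot <- clopperPearson(x[1], n)
            expect_equal(c(spot@lower, spot@upper), 100 * c(lo[1], hi[1]),
                         tolerance = 1e-12)
            expect_gte(mean(lo <= p & p <= hi), 0.94)
        }
    }
})

test_that("cohort-replicate simulation matches binormal closed forms", {
    set.seed(37)
    s <- simulateHemoClassifier(nPos = 39, nNeg = 61, reps = 300)
    expect_lt(abs(s$meanAuc - binormalAuc(36.10, 9.72, 19.20, 5.52)), 0.01)
    expect_lt(abs(s$meanSensPct - 100 * pnorm((36.10 - 24.5) / 9.72)), 2)
    expect_lt(abs(s$meanSpecPct - 100 * pnorm((24.5 - 19.20) / 5.52)), 2)
})
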