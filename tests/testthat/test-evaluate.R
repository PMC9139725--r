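test_that("Dice matches hand-counted overlaps and is symmetric", {
    a <- tinyMask(1:100)
    b <- tinyMask(1:100)
    expect_identical(dice(a, b), 1)
    expect_identical(dice(a, tinyMask(101:200)), 0)
    expect_identical(dice(tinyMask(1:100), tinyMask(26:125)), 0.75)
    expect_identical(dice(tinyMask(26:125), tinyMask(1:100)), 0.75)
    expect_warning(d0 <- dice(tinyMask(integer(0)), tinyMask(integer(0))),
                   "both masks empty")
    expect_identical(d0, 1)
    expect_error(dice(a, tinyMask(1:4, dims = c(6L, 6L, 6L))),
                 "grid mismatch")
})

test_that("Dice is invariant under identical cropping of both masks", {
    p <- testPhantom("simple_pef", 200, seed = 13)
    other <- segMask(imgData(p$mask)[c(2:64, 1), , ],
                     voxelSpacing(p$mask), label = "prediction")
    before <- dice(p$mask, other)
    cr <- cropToChest(p$ct, list(p$mask, other))
    expect_equal(dice(cr$masks[[1]], cr$masks[[2]]), before,
                 tolerance = 1e-12)
})

test_that("Bland-Altman agrees with an independent recomputation", {
    expect_identical(blandAltman(c(1, 2, 3), c(1, 2, 3))$meanDiff, 0)
    expect_identical(blandAltman(c(1, 2, 3), c(1, 2, 3))$loaLower, 0)
    ba <- blandAltman(c(10, 20, 30), c(15, 25, 35))
    expect_identical(c(ba$meanDiff, ba$loaLower, ba$loaUpper),
                     c(-5, -5, -5))
    set.seed(41)
    x <- rnorm(50, 200, 80); y <- x + rnorm(50, 3, 12)
    ba2 <- blandAltman(x, y)
    d <- x - y
    md <- sum(d) / length(d)
    sdd <- sqrt(sum((d - md)^2) / (length(d) - 1))
    expect_equal(ba2$meanDiff, md, tolerance = 1e-10)
    expect_equal(ba2$loaLower, md - 1.96 * sdd, tolerance = 1e-10)
    expect_equal(ba2$loaUpper, md + 1.96 * sdd, tolerance = 1e-10)
    # mean difference equals the difference of means exactly
    expect_equal(ba2$meanDiff, mean(x) - mean(y), tolerance = 1e-12)
    expect_error(blandAltman(1:3, 1:4), "equal length")
})

test_that("ICC recovers known variance-component structure", {
    x <- c(1, 2, 3, 4, 5)
    expect_equal(iccAgreement(x, x)$icc, 1)
    # shuffling destroys pairing
    set.seed(42)
    v <- rnorm(200, 100, 30)
    expect_lt(abs(iccAgreement(v, sample(v))$icc), 0.2)
    # case variance 9, error variance 1 -> ICC ~ 0.9
    set.seed(43)
    truth <- rnorm(500, 0, 3)
    r <- iccAgreement(truth + rnorm(500), truth + rnorm(500))
    expect_lt(abs(r$icc - 0.9), 0.05)
    expect_true(r$lower < r$icc && r$icc < r$upper)
    # no variance anywhere is flagged degenerate
    expect_true(iccAgreement(rep(1, 5), rep(1, 5))$degenerate)
})

test_that("ICC matches a crossed random-effects fit", {
    set.seed(44)
    n <- 200
    case <- rnorm(n, 0, 10)
    rater <- c(0, 3)  # systematic rater offset
    y1 <- case + rater[1] + rnorm(n, 0, 2)
    y2 <- case + rater[2] + rnorm(n, 0, 2)
    ours <- iccAgreement(y1, y2)$icc
    long <- data.frame(y = c(y1, y2),
                       case = factor(rep(seq_len(n), 2)),
                       rater = factor(rep(1:2, each = n)))
    fit <- lme4::lmer(y ~ 1 + (1 | case) + (1 | rater), data = long)
    vc <- as.data.frame(lme4::VarCorr(fit))
    v <- setNames(vc$vcov, vc$grp)
    oracle <- v[["case"]] / (v[["case"]] + v[["rater"]] + v[["Residual"]])
    expect_lt(abs(ours - oracle), 0.02)
})

test_that("Pearson r^2 is sign-blind and detects independence", {
    x <- c(1, 5, 9, 2, 7)
    expect_equal(pearsonR2(x, 2 * x + 3), 1, tolerance = 1e-12)
    expect_equal(pearsonR2(x, -x), 1, tolerance = 1e-12)
    set.seed(45)
    expect_lt(pearsonR2(rnorm(10000), rnorm(10000)), 0.01)
    expect_error(pearsonR2(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("accuracy statistics reproduce exact-interval diagnostics", {
    a <- accuracyStats(rep(c(TRUE, FALSE), each = 10),
                       rep(c(TRUE, FALSE), each = 10))
    expect_identical(a$sensitivity$pct, 100)
    expect_identical(a$specificity$pct, 100)

    # tp=97 fn=3 tn=100 fp=0
    pred <- c(rep(TRUE, 97), rep(FALSE, 3), rep(FALSE, 100))
    truth <- c(rep(TRUE, 100), rep(FALSE, 100))
    a2 <- accuracyStats(pred, truth)
    expect_identical(a2$tp, 97L); expect_identical(a2$fp, 0L)
    expect_identical(a2$tn, 100L); expect_identical(a2$fn, 3L)
    expect_identical(a2$sensitivity$pct, 97)
    expect_lt(abs(a2$sensitivity$ci@lower - 91.48), 0.005)
    expect_lt(abs(a2$sensitivity$ci@upper - 99.38), 0.005)
    expect_lt(abs(a2$specificity$ci@lower - 96.38), 0.005)
    expect_identical(a2$specificity$ci@upper, 100)

    # brute-force confusion counting on random flags
    set.seed(46)
    for (i in 1:10) {
        p <- sample(c(TRUE, FALSE), 50, replace = TRUE)
        t <- sample(c(TRUE, FALSE), 50, replace = TRUE)
        a3 <- accuracyStats(p, t)
        cnt <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
        for (j in 1:50) {
            k <- if (p[j] && t[j]) "tp" else if (p[j]) "fp"
                 else if (t[j]) "fn" else "tn"
            cnt[k] <- cnt[k] + 1L
        }
        expect_identical(c(tp = a3$tp, fp = a3$fp, tn = a3$tn, fn = a3$fn),
                         cnt)
    }

    # one-class truth leaves the other rate undefined, flagged
    a4 <- accuracyStats(c(TRUE, TRUE), c(TRUE, TRUE))
    expect_false(a4$specificity$defined)
})

test_that("subgroup comparisons match reference tests and enumeration", {
    # identical groups: no evidence of a difference
    expect_identical(compareSubgroups(c(1, 2, 3, 4), c(1, 2, 3, 4),
                                      "rank")$pValue, 1)
    # 3-SD shift at n = 50: decisive for both tests
    set.seed(47)
    a <- rnorm(50, 0, 1); b <- rnorm(50, 3, 1)
    expect_lt(compareSubgroups(a, b, "mean")$pValue, 0.001)
    expect_lt(compareSubgroups(a, b, "rank")$pValue, 0.001)
    # Welch agrees with stats::t.test
    tt <- t.test(a, b, var.equal = FALSE)
    ours <- compareSubgroups(a, b, "mean")
    expect_equal(ours$pValue, tt$p.value, tolerance = 1e-12)

    # exhaustive-permutation oracle for small-sample U
    A <- c(1.5, 3.2, 7.1)
    B <- c(2.2, 4.4, 5.5, 9.9)
    res <- compareSubgroups(A, B, "rank")
    pool <- c(A, B)
    nA <- length(A)
    combos <- combn(seq_along(pool), nA)
    uStat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    uAll <- apply(combos, 2, function(idx)
        uStat(pool[idx], pool[-idx]))
    uObs <- uStat(A, B)
    pExact <- min(1, 2 * min(mean(uAll <= uObs), mean(uAll >= uObs)))
    expect_equal(res$statistic, uObs)
    expect_equal(res$pValue, pExact, tolerance = 1e-12)

    expect_error(compareSubgroups(1, c(1, 2), "mean"), "n >= 2")
})

test_that("segmentation evaluation mirrors the agreement battery", {
    d <- withr::local_tempdir()
    man <- generateCohort(2, 3, 0, baseSeed = 21, outDir = d,
                          gridShape = testGrid, spacing = testSpacing)
    # predictions: truth masks shifted by one voxel -> near-perfect but not 1
    predDir <- file.path(d, "pred"); dir.create(predDir)
    preds <- character(nrow(man))
    for (i in seq_len(nrow(man))) {
        img <- RNifti::readNifti(man$mask_path[i])
        arr <- array(as.integer(img), dim = dim(img))
        shifted <- arr[c(2:dim(arr)[1], 1), , ]
        out <- RNifti::asNifti(shifted)
        RNifti::pixdim(out) <- RNifti::pixdim(img)[1:3]
        preds[i] <- file.path(predDir, basename(man$mask_path[i]))
        RNifti::writeNifti(out, preds[i], datatype = "uint8")
    }
    ev <- evaluateSegmentations(preds, man$mask_path,
                                manifest = data.frame(
                                    contrast = man$contrast,
                                    pleural = man$pleural,
                                    class = man$class,
                                    true_volume_ml = man$true_volume_ml))
    expect_identical(ev$overall$n, 5L)
    expect_true(all(ev$perCase$dice > 0 & ev$perCase$dice < 1))
    # a one-voxel cyclic shift preserves volume exactly
    expect_equal(ev$overall$bland_altman$meanDiff, 0, tolerance = 1e-10)
    expect_gt(ev$overall$pearson_r2, 0.99)
})
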