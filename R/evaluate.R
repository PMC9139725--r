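## Agreement and diagnostic-accuracy statistics for pairs of segmentations
## and paired volume series: Dice, Bland-Altman limits of agreement,
## two-way random-effects ICC (absolute agreement, single measure),
## Pearson r^2, confusion-matrix accuracy with exact CIs, and subgroup
## comparisons (Welch t / Mann-Whitney U).

#' Dice overlap coefficient of two masks
#'
#' 2|A n B| / (|A| + |B|).  Two empty masks agree that nothing is present;
#' that case returns 1 with a warning.
#'
#' @param a,b \code{\linkS4class{SegMask}} objects on the same grid.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(a, b) {
    stopifnot(is(a, "SegMask"), is(b, "SegMask"))
    if (!.sameGrid(a, b)) .stopGridMismatch(a, b)
    na <- sum(a@data); nb <- sum(b@data)
    if (na + nb == 0) {
        warning("both masks empty; Dice defined as 1")
        return(1)
    }
    2 * sum(a@data == 1L & b@data == 1L) / (na + nb)
}

#' Bland-Altman analysis of paired volume series
#'
#' Differences x - y; limits of agreement are mean difference +/- 1.96
#' times the sample SD of the differences (n - 1 denominator).
#'
#' @param x,y paired numeric series (e.g. volumes in mL), equal length,
#'   n >= 2.
#' @return list(meanDiff, loaLower, loaUpper, sdDiff, n).
#' @export
blandAltman <- function(x, y) {
    if (length(x) != length(y))
        stop("paired series must have equal length", call. = FALSE)
    if (length(x) < 2) stop("need n >= 2 pairs", call. = FALSE)
    d <- x - y
    m <- mean(d); s <- sd(d)
    list(meanDiff = m, loaLower = m - 1.96 * s, loaUpper = m + 1.96 * s,
         sdDiff = s, n = length(d))
}

#' ICC for absolute agreement of two measurement series
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation (ICC(A,1) in the McGraw-Wong taxonomy) with the F-based
#' 95\% confidence interval.
#'
#' @param x,y paired measurements by two raters, n >= 3.
#' @param level confidence level, default 0.95.
#' @return list(icc, lower, upper, n, degenerate).  When neither rater
#'   shows any variance the estimate is undefined and \code{degenerate}
#'   is TRUE.
#' @export
iccAgreement <- function(x, y, level = 0.95) {
    if (length(x) != length(y))
        stop("paired series must have equal length", call. = FALSE)
    n <- length(x)
    if (n < 3) stop("need n >= 3 pairs", call. = FALSE)
    mat <- cbind(x, y)
    if (var(as.vector(mat)) == 0)
        return(list(icc = NA_real_, lower = NA_real_, upper = NA_real_,
                    n = n, degenerate = TRUE))
    k <- 2L
    grand <- mean(mat)
    rowM <- rowMeans(mat); colM <- colMeans(mat)
    SSR <- k * sum((rowM - grand)^2)
    SSC <- n * sum((colM - grand)^2)
    SST <- sum((mat - grand)^2)
    SSE <- SST - SSR - SSC
    MSR <- SSR / (n - 1); MSC <- SSC / (k - 1)
    MSE <- SSE / ((n - 1) * (k - 1))
    icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))

    ## F-based CI with Satterthwaite df (McGraw & Wong)
    alpha <- 1 - level
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * MSC + b * MSE)^2 /
        ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- qf(1 - alpha / 2, df1 = n - 1, df2 = v)
    FU <- qf(1 - alpha / 2, df1 = v, df2 = n - 1)
    lower <- n * (MSR - FL * MSE) /
        (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    upper <- n * (FU * MSR - MSE) /
        (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    list(icc = icc, lower = lower, upper = upper, n = n,
         degenerate = FALSE)
}

#' Squared Pearson correlation of paired series
#'
#' @param x,y paired numeric series, n >= 3, each with nonzero variance.
#' @return r^2 in [0, 1] (sign-blind by construction).
#' @export
pearsonR2 <- function(x, y) {
    if (length(x) != length(y))
        stop("paired series must have equal length", call. = FALSE)
    if (length(x) < 3) stop("need n >= 3 pairs", call. = FALSE)
    if (var(x) == 0 || var(y) == 0)
        stop("zero variance in one of the series", call. = FALSE)
    cor(x, y)^2
}

#' Diagnostic accuracy from paired decision flags
#'
#' Confusion counts of predicted vs truth flags with sensitivity and
#' specificity in percent, each with an exact
#' \code{\link{clopperPearson}} confidence interval.  When a class is
#' absent from the truth the corresponding rate is undefined (\code{NA},
#' flagged).
#'
#' @param pred,truth logical vectors of equal length.
#' @param level CI level, default 0.95.
#' @return list(tp, fp, tn, fn, sensitivity, specificity) where each rate
#'   is list(pct, ci, defined).
#' @examples
#' accuracyStats(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))
#' @export
accuracyStats <- function(pred, truth, level = 0.95) {
    stopifnot(is.logical(pred), is.logical(truth),
              length(pred) == length(truth))
    tp <- sum(pred & truth); fp <- sum(pred & !truth)
    tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
    rate <- function(success, total) {
        if (total == 0)
            return(list(pct = NA_real_, ci = NULL, defined = FALSE))
        ci <- clopperPearson(success, total, level)
        list(pct = 100 * success / total, ci = ci, defined = TRUE)
    }
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = rate(tp, tp + fn),
         specificity = rate(tn, tn + fp))
}

#' Compare a statistic between two subgroups
#'
#' \code{kind = "mean"}: Welch two-sample t-test.  \code{kind = "rank"}:
#' Mann-Whitney U, by exact enumeration when both groups have at most 8
#' observations and no ties, otherwise by normal approximation with
#' continuity and tie correction.
#'
#' @param valuesA,valuesB numeric vectors, each n >= 2.
#' @param kind \code{"mean"} or \code{"rank"}.
#' @return list(statistic, pValue, kind, nA, nB).  For \code{"rank"} the
#'   statistic is the Mann-Whitney U of group A over group B.
#' @export
compareSubgroups <- function(valuesA, valuesB, kind = c("mean", "rank")) {
    kind <- match.arg(kind)
    if (length(valuesA) < 2 || length(valuesB) < 2)
        stop("both groups need n >= 2", call. = FALSE)
    if (kind == "mean") {
        if (var(valuesA) == 0 && var(valuesB) == 0 &&
            mean(valuesA) == mean(valuesB))
            return(list(statistic = 0, pValue = 1, kind = kind,
                        nA = length(valuesA), nB = length(valuesB)))
        tt <- t.test(valuesA, valuesB, var.equal = FALSE)
        list(statistic = unname(tt$statistic), pValue = tt$p.value,
             kind = kind, nA = length(valuesA), nB = length(valuesB))
    } else {
        small <- length(valuesA) <= 8 && length(valuesB) <= 8
        ties <- anyDuplicated(c(valuesA, valuesB)) > 0
        wt <- suppressWarnings(
            wilcox.test(valuesA, valuesB, exact = small && !ties,
                        correct = TRUE))
        list(statistic = unname(wt$statistic), pValue = min(wt$p.value, 1),
             kind = kind, nA = length(valuesA), nB = length(valuesB))
    }
}

#' Agreement battery for a set of prediction/reference mask pairs
#'
#' Computes per-case Dice and volumes for paired segmentations, then the
#' cohort-level battery: Dice summary, Bland-Altman on volumes, ICC,
#' Pearson r^2, and (when a truth manifest is supplied) subgroup Dice
#' comparisons by contrast, size, class and pleural-effusion status, each
#' with Welch-t and rank p-values.
#'
#' @param predPaths,refPaths equal-length character vectors of NIfTI mask
#'   paths; pair i is compared on the grid of its reference CT-free mask.
#' @param ctPaths optional CT paths used only to define the reference grid;
#'   when omitted the reference mask's own grid is used.
#' @param manifest optional data.frame with one row per pair carrying
#'   \code{contrast}, \code{pleural}, \code{class} and
#'   \code{true_volume_ml} columns for the subgroup splits.
#' @return A list with \code{perCase} (data.frame) and \code{overall} /
#'   \code{subgroups} summaries mirroring a segmentation-evaluation table.
#' @export
evaluateSegmentations <- function(predPaths, refPaths, ctPaths = NULL,
                                  manifest = NULL) {
    stopifnot(length(predPaths) == length(refPaths))
    n <- length(predPaths)
    if (n < 2) stop("need at least two mask pairs", call. = FALSE)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
        refImg <- RNifti::readNifti(refPaths[i])
        ref <- segMask(array(as.numeric(refImg), dim = dim(refImg)),
                       spacing = RNifti::pixdim(refImg)[1:3],
                       label = "reference")
        predImg <- RNifti::readNifti(predPaths[i])
        pred <- segMask(array(as.numeric(predImg), dim = dim(predImg)),
                        spacing = RNifti::pixdim(predImg)[1:3],
                        label = "prediction")
        rows[[i]] <- data.frame(
            dice = dice(pred, ref),
            vol_pred = maskVolumeMl(pred),
            vol_ref = maskVolumeMl(ref))
    }
    perCase <- do.call(rbind, rows)
    overall <- list(
        dice_mean = mean(perCase$dice), dice_sd = sd(perCase$dice),
        dice_median = median(perCase$dice),
        bland_altman = blandAltman(perCase$vol_ref, perCase$vol_pred),
        icc = iccAgreement(perCase$vol_ref, perCase$vol_pred),
        pearson_r2 = pearsonR2(perCase$vol_ref, perCase$vol_pred),
        n = n)
    subgroups <- NULL
    if (!is.null(manifest)) {
        stopifnot(nrow(manifest) == n)
        splitOn <- list(
            contrast = manifest$contrast,
            pleural = manifest$pleural,
            hemopericardium = manifest$class == "hemopericardium",
            large = manifest$true_volume_ml > 50)
        subgroups <- lapply(splitOn, function(flag) {
            if (length(unique(flag)) < 2 || min(table(flag)) < 2)
                return(NULL)
            a <- perCase$dice[flag]; b <- perCase$dice[!flag]
            list(dice_in = mean(a), dice_out = mean(b),
                 t = compareSubgroups(a, b, "mean"),
                 rank = compareSubgroups(a, b, "rank"))
        })
    }
    list(perCase = perCase, overall = overall, subgroups = subgroups)
}
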