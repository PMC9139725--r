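## ROC construction and threshold calibration.
##
## Candidate thresholds are the midpoints between consecutive distinct
## sorted scores, plus one sentinel below the minimum and one above the
## maximum.  A case is called positive when its score is strictly greater
## than the threshold.  On integer-valued attenuation data this midpoint
## rule is what produces half-integer operating thresholds such as 24.5 HU.

#' Empirical ROC curve
#'
#' @param scores numeric scores (here: per-case median HU).
#' @param labels class labels: a logical vector (TRUE = positive), or any
#'   vector combined with \code{positive} naming the positive level.
#' @param positive the positive level of \code{labels} when they are not
#'   logical.
#' @return A \code{\linkS4class{ROCResult}}: candidate thresholds with
#'   empirical sensitivity/specificity at each, and the trapezoidal AUC
#'   (which equals the normalized Mann-Whitney U statistic, ties counted
#'   half).
#' @details At least one case per class is required; a single-class input
#'   is an error.
#' @examples
#' r <- rocCurve(c(30, 40, 10, 20), c(TRUE, TRUE, FALSE, FALSE))
#' rocAuc(r)            # 1: perfect separation
#' youdenThreshold(r)   # 25: midpoint of the separating gap
#' @export
rocCurve <- function(scores, labels, positive = TRUE) {
    stopifnot(length(scores) == length(labels), all(is.finite(scores)))
    lab <- if (is.logical(labels)) labels else labels == positive
    if (anyNA(lab)) stop("labels contain NA", call. = FALSE)
    nPos <- sum(lab); nNeg <- sum(!lab)
    if (nPos == 0 || nNeg == 0)
        stop("need at least one positive and one negative case",
             call. = FALSE)
    pos <- sort(scores[lab]); neg <- sort(scores[!lab])
    u <- sort(unique(scores))
    thr <- c(u[1] - 1,
             if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
             u[length(u)] + 1)
    sens <- (nPos - findInterval(thr, pos)) / nPos   # P(score > thr | pos)
    spec <- findInterval(thr, neg) / nNeg            # P(score <= thr | neg)
    fpr <- rev(1 - spec); tpr <- rev(sens)           # ascending FPR
    auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
    new("ROCResult", thresholds = thr, sensitivity = sens,
        specificity = spec, auc = min(max(auc, 0), 1),
        nPos = as.integer(nPos), nNeg = as.integer(nNeg))
}

#' Youden-optimal operating threshold
#'
#' The candidate threshold maximizing Youden's J = sensitivity +
#' specificity - 1; ties are broken toward the smallest threshold (which
#' maximizes sensitivity among the tied optima).
#'
#' @param roc a \code{\linkS4class{ROCResult}}.
#' @return The selected threshold.
#' @export
youdenThreshold <- function(roc) {
    stopifnot(is(roc, "ROCResult"))
    j <- roc@sensitivity + roc@specificity - 1
    roc@thresholds[which.max(j)]
}

#' Closest-top-left operating threshold
#'
#' The candidate threshold minimizing the squared Euclidean distance
#' (1 - sensitivity)^2 + (1 - specificity)^2 from the ROC point to the
#' perfect classifier; ties toward the smallest threshold.
#'
#' @param roc a \code{\linkS4class{ROCResult}}.
#' @return The selected threshold.
#' @export
topLeftThreshold <- function(roc) {
    stopifnot(is(roc, "ROCResult"))
    d2 <- (1 - roc@sensitivity)^2 + (1 - roc@specificity)^2
    roc@thresholds[which.min(d2)]
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval from Beta quantiles:
#' lower = qbeta(alpha/2, s, n-s+1), upper = qbeta(1-alpha/2, s+1, n-s),
#' with the one-sided closed forms at the boundaries (s = 0 fixes the lower
#' bound at 0; s = n fixes the upper bound at 100\%).
#'
#' @param successes,trials counts, 0 <= successes <= trials, trials >= 1.
#' @param level confidence level, default 0.95.
#' @return A \code{\linkS4class{BinomialCI}} (bounds in percent).
#' @examples
#' clopperPearson(97, 100)   # 97.00% (91.48-99.38%)
#' clopperPearson(22, 22)    # 100.00% (84.56-100.00%)
#' @export
clopperPearson <- function(successes, trials, level = 0.95) {
    s <- as.integer(successes); n <- as.integer(trials)
    if (is.na(s) || is.na(n) || n < 1L || s < 0L || s > n)
        stop("need integer counts with 0 <= successes <= trials, trials >= 1",
             call. = FALSE)
    if (level <= 0 || level >= 1)
        stop("level must be in (0, 1)", call. = FALSE)
    a <- (1 - level) / 2
    lower <- if (s == 0L) 0 else qbeta(a, s, n - s + 1)
    upper <- if (s == n)  1 else qbeta(1 - a, s + 1, n - s)
    new("BinomialCI", successes = s, trials = n, level = level,
        estimate = 100 * s / n, lower = 100 * lower, upper = 100 * upper)
}

#' Bootstrap AUC confidence interval (approximation)
#'
#' Stratified nonparametric bootstrap percentile interval for the AUC.
#' This is a labelled approximation offered for exploratory use; it is not
#' an exact or DeLong interval.
#'
#' @param scores,labels,positive as in \code{\link{rocCurve}}.
#' @param reps bootstrap replicates, default 2000.
#' @param level confidence level, default 0.95.
#' @return list(auc, lower, upper, reps, method = "bootstrap percentile").
#' @export
bootstrapAucCi <- function(scores, labels, positive = TRUE, reps = 2000,
                           level = 0.95) {
    lab <- if (is.logical(labels)) labels else labels == positive
    pos <- scores[lab]; neg <- scores[!lab]
    base <- rocCurve(scores, lab)@auc
    aucs <- vapply(seq_len(reps), function(i) {
        p <- sample(pos, replace = TRUE)
        q <- sample(neg, replace = TRUE)
        rocCurve(c(p, q), rep(c(TRUE, FALSE), c(length(p), length(q))))@auc
    }, numeric(1))
    qs <- quantile(aucs, c((1 - level) / 2, 1 - (1 - level) / 2),
                   names = FALSE)
    list(auc = base, lower = qs[1], upper = qs[2], reps = reps,
         method = "bootstrap percentile")
}

#' Closed-form AUC of the binormal classifier
#'
#' For scores N(muPos, sdPos^2) vs N(muNeg, sdNeg^2) the population AUC is
#' Phi((muPos - muNeg) / sqrt(sdPos^2 + sdNeg^2)).
#'
#' @param muPos,sdPos,muNeg,sdNeg class parameters.
#' @return The analytic AUC.
#' @export
binormalAuc <- function(muPos, sdPos, muNeg, sdNeg)
    stats::pnorm((muPos - muNeg) / sqrt(sdPos^2 + sdNeg^2))

#' Density-crossing point of two normal classes
#'
#' The Youden-optimal population threshold is the point between the class
#' means where the two class densities are equal; solved numerically.
#'
#' @param muPos,sdPos,muNeg,sdNeg class parameters (muNeg < muPos).
#' @return The crossing point between the two means.
#' @export
binormalDensityCrossing <- function(muPos, sdPos, muNeg, sdNeg) {
    stopifnot(muNeg < muPos)
    f <- function(x) dnorm(x, muPos, sdPos) - dnorm(x, muNeg, sdNeg)
    uniroot(f, lower = muNeg, upper = muPos, tol = 1e-10)$root
}

#' Cohort-replicate simulation of the median-HU hemopericardium classifier
#'
#' Draws per-case median attenuation scores for a positive (hemopericardium)
#' and a negative (simple effusion) class from normal distributions, builds
#' the empirical ROC per replicate cohort, applies the fixed HU cutoff, and
#' averages over replicates.  Defaults reproduce the study conditions:
#' cohorts of 39/61 with the pooled class statistics of
#' \code{\link{huClassStats}} and the 24.5 HU cutoff.
#'
#' @param nPos,nNeg class sizes per replicate cohort.
#' @param reps number of replicate cohorts.
#' @param cutoffHu fixed decision threshold applied per replicate
#'   (positive call when score > cutoff).
#' @param muPos,sdPos,muNeg,sdNeg class score distributions (HU).
#' @return list(meanAuc, meanSensPct, meanSpecPct, meanYouden, reps, nPos,
#'   nNeg, cutoffHu).  Sensitivity/specificity in percent.
#' @details Uses the current RNG state; seed it with \code{set.seed} for
#'   reproducibility.
#' @export
simulateHemoClassifier <- function(nPos = 39L, nNeg = 61L, reps = 1000L,
                                   cutoffHu = 24.5,
                                   muPos = huClassStats()$hemopericardium$pooled["mean"],
                                   sdPos = huClassStats()$hemopericardium$pooled["sd"],
                                   muNeg = huClassStats()$simple_pef$pooled["mean"],
                                   sdNeg = huClassStats()$simple_pef$pooled["sd"]) {
    stopifnot(nPos >= 1, nNeg >= 1, reps >= 1)
    lab <- rep(c(TRUE, FALSE), c(nPos, nNeg))
    auc <- sens <- spec <- yj <- numeric(reps)
    for (i in seq_len(reps)) {
        pos <- rnorm(nPos, muPos, sdPos)
        neg <- rnorm(nNeg, muNeg, sdNeg)
        r <- rocCurve(c(pos, neg), lab)
        auc[i] <- r@auc
        yj[i] <- youdenThreshold(r)
        sens[i] <- mean(pos > cutoffHu)
        spec[i] <- mean(neg <= cutoffHu)
    }
    list(meanAuc = mean(auc), meanSensPct = 100 * mean(sens),
         meanSpecPct = 100 * mean(spec), meanYouden = mean(yj),
         reps = reps, nPos = as.integer(nPos), nNeg = as.integer(nNeg),
         cutoffHu = cutoffHu)
}
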