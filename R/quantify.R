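## Per-case quantification: voxel-count volumetry, range-filtered HU
## extraction, the median-HU statistic, and the decision rules.
##
## Decision semantics (all strict): effusion present when volume > 50 mL,
## large effusion when volume > 100 mL, hemopericardium when the filtered
## median attenuation exceeds 24.5 HU, alert when hemopericardium OR a
## large effusion is present.  The half-integer HU cutoff makes equality
## impossible on integer-valued CTs, so strictness only matters for the
## volume rules.

#' Decision thresholds for effusion classification
#'
#' @param volumeMl effusion-present cutoff (mL), default 50.
#' @param largeMl large-effusion cutoff (mL), default 100.
#' @param hu hemopericardium cutoff on the filtered median attenuation
#'   (HU), default 24.5.
#' @param huLo,huHi inclusive attenuation filter bounds retaining the
#'   fluid/blood range, defaults 0 and 80 HU.
#' @return A named list of thresholds as used by \code{\link{classifyCase}}.
#' @export
pefThresholds <- function(volumeMl = 50, largeMl = 100, hu = 24.5,
                          huLo = 0, huHi = 80) {
    stopifnot(volumeMl >= 0, largeMl >= volumeMl, huLo <= huHi)
    list(volumeMl = volumeMl, largeMl = largeMl, hu = hu,
         huLo = huLo, huHi = huHi)
}

#' Effusion volume of a mask, in millilitres
#'
#' @param mask a \code{\linkS4class{SegMask}}.
#' @return Nonzero-voxel count times the per-voxel volume; 0 for an empty
#'   mask.
#' @export
maskVolumeMl <- function(mask) {
    stopifnot(is(mask, "SegMask"))
    sum(mask@data) * voxelVolumeMl(mask@spacing)
}

#' Extract range-filtered attenuation values inside a mask
#'
#' Collects the HU value of every mask voxel and keeps those inside the
#' inclusive fluid/blood window \code{[lo, hi]}; values outside it belong
#' to other tissue classes and are discarded before the median is taken.
#'
#' @param ct a \code{\linkS4class{CTVolume}}.
#' @param mask a \code{\linkS4class{SegMask}} on the same grid.
#' @param lo,hi inclusive filter bounds (HU), defaults 0 and 80.
#' @return Numeric vector of retained HU values (order is not part of the
#'   contract).
#' @export
extractFilteredHu <- function(ct, mask, lo = 0, hi = 80) {
    stopifnot(is(ct, "CTVolume"), is(mask, "SegMask"))
    if (!.sameGrid(ct, mask)) .stopGridMismatch(ct, mask)
    v <- ct@data[mask@data == 1L]
    v[v >= lo & v <= hi]
}

#' Median attenuation
#'
#' Sample median (even counts average the two central order statistics).
#' An empty input yields \code{NA}, the undefined sentinel propagated into
#' the case report.
#'
#' @param values numeric vector of HU values (may be empty).
#' @return The median HU, or \code{NA_real_} when no value is available.
#' @export
medianHu <- function(values) {
    if (length(values) == 0) return(NA_real_)
    median(values)
}

#' Classify one case from its CT and segmentation mask
#'
#' Computes the effusion volume and the range-filtered median attenuation,
#' then applies the decision rules.  When no voxel survives the filter the
#' median is undefined and the hemopericardium flag is FALSE (no evidence
#' of blood).
#'
#' @param ct a \code{\linkS4class{CTVolume}}.
#' @param mask a \code{\linkS4class{SegMask}} on the same grid.
#' @param thresholds see \code{\link{pefThresholds}}.
#' @param caseId identifier carried into the report.
#' @return A \code{\linkS4class{PEFReport}}.
#' @examples
#' ct <- ctVolume(array(36, c(16, 16, 16)), c(4, 4, 4))
#' m <- segMask(array(1L, c(16, 16, 16)), c(4, 4, 4), label = "truth")
#' classifyCase(ct, m, caseId = "demo")
#' @export
classifyCase <- function(ct, mask, thresholds = pefThresholds(),
                         caseId = "case") {
    stopifnot(is(ct, "CTVolume"), is(mask, "SegMask"))
    if (!.sameGrid(ct, mask)) .stopGridMismatch(ct, mask)
    nVox <- sum(mask@data)
    volMl <- nVox * voxelVolumeMl(mask@spacing)
    hu <- extractFilteredHu(ct, mask, lo = thresholds$huLo,
                            hi = thresholds$huHi)
    med <- medianHu(hu)
    pef <- volMl > thresholds$volumeMl
    large <- volMl > thresholds$largeMl
    hemo <- !is.na(med) && med > thresholds$hu
    new("PEFReport", caseId = caseId, volumeMl = volMl,
        nVoxels = as.integer(nVox), medianHu = med,
        nFilteredOut = as.integer(nVox - length(hu)),
        pefPresent = pef, largePef = large, hemopericardium = hemo,
        alert = hemo || large, thresholds = thresholds)
}
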