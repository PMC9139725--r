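## Core S4 containers.  All image-like objects carry their voxel spacing in
## millimetres; nothing in the package ever resamples silently, so a grid
## mismatch between a volume and a mask is always an error, never a warning.

.MASK_LABELS <- c("reference", "prediction", "reader1", "reader2", "truth")
.EFFUSION_CLASSES <- c("none", "simple_pef", "hemopericardium")

#' CTVolume: a 3-D CT attenuation volume
#'
#' Holds a 3-D array of attenuation values in Hounsfield units (HU) together
#' with the voxel spacing in millimetres and the axis-orientation string
#' carried from the NIfTI header (e.g. \code{"RAS"}).
#'
#' Validity requires a 3-D array of finite values and strictly positive,
#' finite spacing.  Values outside the plausible CT range [-1100, 3100] HU do
#' not invalidate the object; the \code{\link{ctVolume}} constructor emits a
#' warning for them instead.
#'
#' @slot data 3-D numeric array of HU values.
#' @slot spacing numeric(3), voxel edge lengths (dx, dy, dz) in mm.
#' @slot orientation length-1 character, axis-direction metadata.
#' @seealso \code{\link{ctVolume}}, \code{\link{loadVolume}}
#' @exportClass CTVolume
setClass("CTVolume",
         representation(data = "array", spacing = "numeric",
                        orientation = "character"))

setValidity("CTVolume", function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
        msg <- c(msg, "data must be a 3-D array")
    if (length(object@spacing) != 3L ||
        !all(is.finite(object@spacing)) || any(object@spacing <= 0))
        msg <- c(msg, "spacing must be three strictly positive finite values (mm)")
    if (!all(is.finite(object@data)))
        msg <- c(msg, "HU values must all be finite")
    if (length(object@orientation) != 1L)
        msg <- c(msg, "orientation must be a single string")
    if (length(msg)) msg else TRUE
})

#' SegMask: a binary segmentation mask
#'
#' A binary (0/1) 3-D array on the same voxel grid as its paired
#' \code{\linkS4class{CTVolume}}, labelled by provenance
#' (\code{"reference"}, \code{"prediction"}, \code{"reader1"},
#' \code{"reader2"} or \code{"truth"}).
#'
#' @slot data 3-D integer array with values in \{0, 1\}.
#' @slot spacing numeric(3), voxel edge lengths in mm.
#' @slot label provenance label.
#' @seealso \code{\link{segMask}}, \code{\link{loadMask}}
#' @exportClass SegMask
setClass("SegMask",
         representation(data = "array", spacing = "numeric",
                        label = "character"))

setValidity("SegMask", function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
        msg <- c(msg, "data must be a 3-D array")
    if (!all(object@data %in% c(0L, 1L)))
        msg <- c(msg, "mask values must be 0 or 1 only")
    if (length(object@spacing) != 3L ||
        !all(is.finite(object@spacing)) || any(object@spacing <= 0))
        msg <- c(msg, "spacing must be three strictly positive finite values (mm)")
    if (length(object@label) != 1L || !object@label %in% .MASK_LABELS)
        msg <- c(msg, paste0("label must be one of: ",
                             paste(.MASK_LABELS, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' PEFReport: per-case quantification result
#'
#' The per-case output of \code{\link{classifyCase}}: effusion volume,
#' filtered median HU, and the four decision flags (effusion present,
#' large effusion, hemopericardium, alert) together with the thresholds
#' that produced them.
#'
#' @slot caseId case identifier.
#' @slot volumeMl effusion volume in mL (voxel count times voxel volume).
#' @slot nVoxels number of mask voxels.
#' @slot medianHu median of the range-filtered HU values inside the mask;
#'   \code{NA} when no voxel survives the filter.
#' @slot nFilteredOut number of mask voxels removed by the HU range filter.
#' @slot pefPresent,largePef,hemopericardium,alert decision flags.
#' @slot thresholds list of thresholds used (see \code{\link{pefThresholds}}).
#' @exportClass PEFReport
setClass("PEFReport",
         representation(caseId = "character", volumeMl = "numeric",
                        nVoxels = "integer", medianHu = "numeric",
                        nFilteredOut = "integer", pefPresent = "logical",
                        largePef = "logical", hemopericardium = "logical",
                        alert = "logical", thresholds = "list"))

setValidity("PEFReport", function(object) {
    msg <- character()
    if (object@largePef && !object@pefPresent)
        msg <- c(msg, "largePef implies pefPresent")
    if (is.na(object@medianHu) && object@hemopericardium)
        msg <- c(msg, "hemopericardium must be FALSE when medianHu is undefined")
    if (object@volumeMl < 0) msg <- c(msg, "volumeMl must be >= 0")
    if (length(msg)) msg else TRUE
})

#' ROCResult: an empirical ROC curve
#'
#' Candidate thresholds (midpoints between consecutive distinct scores plus
#' sentinels beyond the observed range), the empirical sensitivity and
#' specificity at each, and the trapezoidal AUC.  A case is called positive
#' when its score is strictly greater than the threshold.
#'
#' @slot thresholds sorted candidate thresholds.
#' @slot sensitivity,specificity empirical operating characteristics per
#'   threshold.
#' @slot auc area under the empirical curve (trapezoidal rule).
#' @slot nPos,nNeg class sizes.
#' @seealso \code{\link{rocCurve}}, \code{\link{youdenThreshold}},
#'   \code{\link{topLeftThreshold}}
#' @exportClass ROCResult
setClass("ROCResult",
         representation(thresholds = "numeric", sensitivity = "numeric",
                        specificity = "numeric", auc = "numeric",
                        nPos = "integer", nNeg = "integer"))

setValidity("ROCResult", function(object) {
    msg <- character()
    n <- length(object@thresholds)
    if (length(object@sensitivity) != n || length(object@specificity) != n)
        msg <- c(msg, "thresholds, sensitivity and specificity must have equal length")
    if (is.unsorted(object@thresholds, strictly = TRUE))
        msg <- c(msg, "thresholds must be strictly increasing")
    if (any(diff(object@sensitivity) > 1e-12))
        msg <- c(msg, "sensitivity must be non-increasing in the threshold")
    if (object@auc < 0 || object@auc > 1)
        msg <- c(msg, "auc must lie in [0, 1]")
    if (object@nPos < 1L || object@nNeg < 1L)
        msg <- c(msg, "both classes must be represented")
    if (length(msg)) msg else TRUE
})

#' BinomialCI: an exact binomial confidence interval
#'
#' Clopper-Pearson (Beta-quantile) exact interval for a binomial
#' proportion, expressed in percent.
#'
#' @slot successes,trials counts.
#' @slot level confidence level (fraction).
#' @slot estimate,lower,upper point estimate and bounds, in percent.
#' @seealso \code{\link{clopperPearson}}
#' @exportClass BinomialCI
setClass("BinomialCI",
         representation(successes = "integer", trials = "integer",
                        level = "numeric", estimate = "numeric",
                        lower = "numeric", upper = "numeric"))

setValidity("BinomialCI", function(object) {
    msg <- character()
    if (object@successes < 0L || object@successes > object@trials)
        msg <- c(msg, "need 0 <= successes <= trials")
    if (object@trials < 1L) msg <- c(msg, "trials must be >= 1")
    if (!(object@lower <= object@estimate + 1e-9 &&
          object@estimate <= object@upper + 1e-9 &&
          object@lower >= 0 && object@upper <= 100))
        msg <- c(msg, "need 0 <= lower <= estimate <= upper <= 100")
    if (object@successes == object@trials && object@upper != 100)
        msg <- c(msg, "upper bound must be 100 when successes == trials")
    if (object@successes == 0L && object@lower != 0)
        msg <- c(msg, "lower bound must be 0 when successes == 0")
    if (length(msg)) msg else TRUE
})

#' PhantomSpec: parameters of one synthetic thoracic phantom
#'
#' Fully determines one phantom: grid geometry, effusion class and target
#' volume, contrast and pleural-effusion flags, voxel noise, and the seed.
#' The same spec always generates bit-identical output.
#'
#' @slot gridShape integer(3) voxel grid dimensions.
#' @slot spacing numeric(3) voxel spacing in mm.
#' @slot effusionClass one of \code{"none"}, \code{"simple_pef"},
#'   \code{"hemopericardium"}.
#' @slot targetVolumeMl target truth-mask volume in mL.  Negatives carry a
#'   small physiological rim (< 50 mL), so 0 is not required for class
#'   \code{"none"}.
#' @slot contrast,pleuralEffusion scenario flags.
#' @slot noiseSdHu standard deviation of the global Gaussian voxel noise, HU.
#' @slot perCaseMeanHu effusion attenuation for this case; \code{NA} means
#'   draw it from the class distribution (see \code{\link{huClassStats}}).
#' @slot seed integer seed; fully determines the output.
#' @slot keepScene when TRUE, \code{\link{generatePhantom}} additionally
#'   returns the painted scene components (trunk, lungs, heart, pleural
#'   region) for geometric verification.
#' @seealso \code{\link{phantomSpec}}, \code{\link{generatePhantom}}
#' @exportClass PhantomSpec
setClass("PhantomSpec",
         representation(gridShape = "integer", spacing = "numeric",
                        effusionClass = "character",
                        targetVolumeMl = "numeric", contrast = "logical",
                        pleuralEffusion = "logical", noiseSdHu = "numeric",
                        perCaseMeanHu = "numeric", seed = "integer",
                        keepScene = "logical"))

setValidity("PhantomSpec", function(object) {
    msg <- character()
    if (length(object@gridShape) != 3L || any(object@gridShape < 16L))
        msg <- c(msg, "gridShape must be three dimensions of at least 16 voxels")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
        msg <- c(msg, "spacing must be three positive values (mm)")
    if (!object@effusionClass %in% .EFFUSION_CLASSES)
        msg <- c(msg, paste0("effusionClass must be one of: ",
                             paste(.EFFUSION_CLASSES, collapse = ", ")))
    if (object@targetVolumeMl < 0)
        msg <- c(msg, "targetVolumeMl must be >= 0")
    if (object@noiseSdHu < 0)
        msg <- c(msg, "noiseSdHu must be >= 0")
    if (is.na(object@seed))
        msg <- c(msg, "seed must be set")
    if (length(msg)) msg else TRUE
})

#' CropBox: an axis-aligned voxel crop
#'
#' Inclusive per-axis voxel index ranges of a chest crop, with the margin
#' (mm) that was applied around the lung bounding box.
#'
#' @slot xRange,yRange,zRange integer(2) inclusive index ranges.
#' @slot marginMm symmetric margin applied, in mm.
#' @seealso \code{\link{cropToChest}}
#' @exportClass CropBox
setClass("CropBox",
         representation(xRange = "integer", yRange = "integer",
                        zRange = "integer", marginMm = "numeric"))

setValidity("CropBox", function(object) {
    rng <- list(object@xRange, object@yRange, object@zRange)
    bad <- vapply(rng, function(r)
        length(r) != 2L || any(r < 1L) || r[1] > r[2], logical(1))
    if (any(bad)) "each range must be two indices with lower <= upper, >= 1"
    else if (object@marginMm < 0) "marginMm must be >= 0"
    else TRUE
})
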