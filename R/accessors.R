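## Constructors, accessors and show() methods.  Slots are never touched
## directly by user code; these are the supported surface.

#' Construct a CTVolume
#'
#' @param data 3-D numeric array of attenuation values in HU.
#' @param spacing numeric(3), voxel spacing (dx, dy, dz) in mm.
#' @param orientation axis-direction string carried from (or written to) the
#'   NIfTI header; default \code{"RAS"}.
#' @return A \code{\linkS4class{CTVolume}}.  Values outside the plausible CT
#'   range [-1100, 3100] HU trigger a warning but are kept unchanged.
#' @examples
#' ct <- ctVolume(array(0, c(16, 16, 16)), spacing = c(1, 1, 1))
#' voxelSpacing(ct)
#' @export
ctVolume <- function(data, spacing, orientation = "RAS") {
    storage.mode(data) <- "double"
    obj <- new("CTVolume", data = data, spacing = as.numeric(spacing),
               orientation = orientation)
    rng <- range(data)
    if (rng[1] < -1100 || rng[2] > 3100)
        warning(sprintf("HU values outside plausible CT range [-1100, 3100]: observed [%g, %g]",
                        rng[1], rng[2]))
    obj
}

#' Construct a SegMask
#'
#' Any nonzero voxel is coerced to 1 (with a warning when values other than
#' 0/1 are present), matching how segmentation masks with label values are
#' interpreted downstream.
#'
#' @param data 3-D array; nonzero entries become 1.
#' @param spacing numeric(3), voxel spacing in mm.
#' @param label provenance label, one of \code{"reference"},
#'   \code{"prediction"}, \code{"reader1"}, \code{"reader2"}, \code{"truth"}.
#' @return A \code{\linkS4class{SegMask}}.
#' @export
segMask <- function(data, spacing, label = "reference") {
    if (!all(data %in% c(0, 1))) {
        warning("mask contains values other than {0, 1}; coercing nonzero to 1")
        data <- (data != 0)
    }
    storage.mode(data) <- "integer"
    new("SegMask", data = data, spacing = as.numeric(spacing), label = label)
}

#' @describeIn imgData HU array of a CT volume.
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))

#' Image data and geometry accessors
#'
#' @param x a \code{\linkS4class{CTVolume}} or \code{\linkS4class{SegMask}}.
#' @return \code{imgData}: the underlying 3-D array; \code{voxelSpacing}:
#'   numeric(3) in mm; \code{axisOrientation}: orientation string;
#'   \code{maskLabel}: the mask's provenance label.
#' @name imgData
#' @aliases voxelSpacing axisOrientation maskLabel
#' @export
setMethod("imgData", "CTVolume", function(x) x@data)

#' @rdname imgData
#' @export
setMethod("imgData", "SegMask", function(x) x@data)

#' @rdname imgData
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname imgData
#' @export
setMethod("voxelSpacing", "CTVolume", function(x) x@spacing)

#' @rdname imgData
#' @export
setMethod("voxelSpacing", "SegMask", function(x) x@spacing)

#' @rdname imgData
#' @export
setGeneric("axisOrientation", function(x) standardGeneric("axisOrientation"))

#' @rdname imgData
#' @export
setMethod("axisOrientation", "CTVolume", function(x) x@orientation)

#' @rdname imgData
#' @export
setGeneric("maskLabel", function(x) standardGeneric("maskLabel"))

#' @rdname imgData
#' @export
setMethod("maskLabel", "SegMask", function(x) x@label)

setMethod("show", "CTVolume", function(object) {
    d <- dim(object@data)
    cat(sprintf("CTVolume: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm (%s)\n",
                d[1], d[2], d[3], object@spacing[1], object@spacing[2],
                object@spacing[3], object@orientation))
    cat(sprintf("  HU range [%g, %g]\n", min(object@data), max(object@data)))
})

setMethod("show", "SegMask", function(object) {
    d <- dim(object@data)
    cat(sprintf("SegMask (%s): %d x %d x %d voxels, %d foreground (%.2f mL)\n",
                object@label, d[1], d[2], d[3], sum(object@data),
                sum(object@data) * prod(object@spacing) / 1000))
})

setMethod("show", "PEFReport", function(object) {
    cat(sprintf("PEFReport [%s]\n", object@caseId))
    cat(sprintf("  volume: %.1f mL (%d voxels); median HU: %s (%d filtered out)\n",
                object@volumeMl, object@nVoxels,
                if (is.na(object@medianHu)) "undefined"
                else sprintf("%.2f", object@medianHu),
                object@nFilteredOut))
    cat(sprintf("  PEF > %g mL: %s | large (> %g mL): %s | hemopericardium (HU > %g): %s | alert: %s\n",
                object@thresholds$volumeMl, object@pefPresent,
                object@thresholds$largeMl, object@largePef,
                object@thresholds$hu, object@hemopericardium, object@alert))
})

setMethod("show", "ROCResult", function(object) {
    cat(sprintf("ROCResult: %d thresholds, %d pos / %d neg, AUC = %.4f\n",
                length(object@thresholds), object@nPos, object@nNeg,
                object@auc))
})

setMethod("show", "BinomialCI", function(object) {
    cat(sprintf("%d/%d = %.2f%% (%.0f%% CI %.2f-%.2f%%)\n",
                object@successes, object@trials, object@estimate,
                100 * object@level, object@lower, object@upper))
})

setMethod("show", "PhantomSpec", function(object) {
    cat(sprintf("PhantomSpec: %s, target %.0f mL, grid %s @ %s mm, contrast=%s, pleural=%s, noise %.1f HU, seed %d\n",
                object@effusionClass, object@targetVolumeMl,
                paste(object@gridShape, collapse = "x"),
                paste(object@spacing, collapse = "x"),
                object@contrast, object@pleuralEffusion, object@noiseSdHu,
                object@seed))
})

setMethod("show", "CropBox", function(object) {
    cat(sprintf("CropBox: x %d-%d, y %d-%d, z %d-%d (margin %.0f mm)\n",
                object@xRange[1], object@xRange[2], object@yRange[1],
                object@yRange[2], object@zRange[1], object@zRange[2],
                object@marginMm))
})

#' ROC accessors
#'
#' @param x a \code{\linkS4class{ROCResult}}.
#' @return \code{rocAuc}: the trapezoidal AUC; \code{rocTable}: a data.frame
#'   with threshold, sensitivity and specificity columns.
#' @name rocAuc
#' @export
setGeneric("rocAuc", function(x) standardGeneric("rocAuc"))

#' @rdname rocAuc
#' @export
setMethod("rocAuc", "ROCResult", function(x) x@auc)

#' @rdname rocAuc
#' @export
setGeneric("rocTable", function(x) standardGeneric("rocTable"))

#' @rdname rocAuc
#' @export
setMethod("rocTable", "ROCResult", function(x)
    data.frame(threshold = x@thresholds, sensitivity = x@sensitivity,
               specificity = x@specificity))

#' Convert a PEFReport to a one-row data.frame
#'
#' @param x a \code{\linkS4class{PEFReport}}.
#' @param row.names,optional,... passed through for generic compatibility.
#' @return A one-row data.frame with the report fields flattened; used to
#'   assemble the cohort CSV.
#' @export
as.data.frame.PEFReport <- function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(case_id = x@caseId, volume_ml = x@volumeMl,
               n_voxels = x@nVoxels, median_hu = x@medianHu,
               n_filtered_out = x@nFilteredOut, pef_present = x@pefPresent,
               large_pef = x@largePef, hemopericardium = x@hemopericardium,
               alert = x@alert,
               thr_volume_ml = x@thresholds$volumeMl,
               thr_large_ml = x@thresholds$largeMl,
               thr_hu = x@thresholds$hu,
               thr_hu_lo = x@thresholds$huLo,
               thr_hu_hi = x@thresholds$huHi,
               stringsAsFactors = FALSE)
}

## internal: grid compatibility (dims exact, spacing to float32 round-off)
.sameGrid <- function(a, b) {
    identical(dim(a@data), dim(b@data)) &&
        all(abs(a@spacing - b@spacing) <= 1e-5 * pmax(a@spacing, b@spacing))
}

.stopGridMismatch <- function(a, b, what = "mask") {
    stop(sprintf("grid mismatch: %s grid %s @ (%s) mm vs reference %s @ (%s) mm",
                 what,
                 paste(dim(b@data), collapse = "x"),
                 paste(signif(b@spacing, 6), collapse = ", "),
                 paste(dim(a@data), collapse = "x"),
                 paste(signif(a@spacing, 6), collapse = ", ")),
         call. = FALSE)
}
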