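## Classical chest cropping: threshold-based lung extraction followed by a
## bounding-box crop with a symmetric physical margin.  Cropping slices the
## arrays; it never touches HU values and never resamples.

#' Extract a lung mask by thresholding and connected components
#'
#' Voxels below -500 HU that are not connected to the array border
#' (i.e. internal air) are labelled by 6-connected components and the two
#' largest components are returned as the lungs.
#'
#' @param ct a \code{\linkS4class{CTVolume}}.
#' @param thresholdHu air/parenchyma threshold; default -500 HU.
#' @return A \code{\linkS4class{SegMask}} (label \code{"prediction"}).  If
#'   no internal air component exists the mask is empty and a warning is
#'   emitted (no error).
#' @export
extractLungMask <- function(ct, thresholdHu = -500) {
    stopifnot(is(ct, "CTVolume"))
    dims <- dim(ct@data)
    fg <- ct@data < thresholdHu
    lab <- cc_label_3d(as.logical(fg), as.integer(dims))
    border <- unique(c(lab[1, , ], lab[dims[1], , ],
                       lab[, 1, ], lab[, dims[2], ],
                       lab[, , 1], lab[, , dims[3]]))
    border <- border[border > 0]
    sizes <- tabulate(lab)
    keep <- setdiff(which(sizes > 0), border)
    if (length(keep) == 0) {
        warning("no internal air component found; returning empty lung mask")
        return(segMask(array(0L, dims), spacing = ct@spacing,
                       label = "prediction"))
    }
    keep <- keep[order(sizes[keep], decreasing = TRUE)]
    keep <- keep[seq_len(min(2L, length(keep)))]
    segMask(array(as.integer(lab %in% keep), dims), spacing = ct@spacing,
            label = "prediction")
}

#' Crop a CT (and co-registered masks) to the chest region
#'
#' Takes the axis-aligned bounding box of the lung mask, dilates it by
#' \code{marginMm} on every side (converted to voxels per axis, rounded
#' up), clamps it to the grid, and slices the CT and every supplied mask
#' identically.  HU values are unchanged; cropping a cropped volume with
#' the same margin is the identity.
#'
#' @param ct a \code{\linkS4class{CTVolume}}.
#' @param masks list of \code{\linkS4class{SegMask}} on the same grid,
#'   cropped along with the CT.
#' @param marginMm symmetric margin around the lung bounding box, mm.
#' @param lungMask the lung \code{\linkS4class{SegMask}}; computed from
#'   \code{ct} via \code{\link{extractLungMask}} when not supplied.
#' @return A list with \code{ct}, \code{masks} (both cropped), and
#'   \code{box} (a \code{\linkS4class{CropBox}}).  With an empty lung mask
#'   the inputs are returned uncropped with a warning and a full-grid box.
#' @export
cropToChest <- function(ct, masks = list(), marginMm = 20,
                        lungMask = extractLungMask(ct)) {
    stopifnot(is(ct, "CTVolume"), marginMm >= 0)
    if (is(masks, "SegMask")) masks <- list(masks)
    for (m in masks)
        if (!.sameGrid(ct, m)) .stopGridMismatch(ct, m)
    dims <- dim(ct@data)
    if (sum(lungMask@data) == 0) {
        warning("empty lung mask; returning input uncropped")
        box <- new("CropBox", xRange = c(1L, dims[1]),
                   yRange = c(1L, dims[2]), zRange = c(1L, dims[3]),
                   marginMm = as.numeric(marginMm))
        return(list(ct = ct, masks = masks, box = box))
    }
    idx <- which(lungMask@data == 1, arr.ind = TRUE)
    marginVox <- ceiling(marginMm / ct@spacing)
    lohi <- lapply(seq_len(3), function(ax) {
        lo <- max(1L, min(idx[, ax]) - marginVox[ax])
        hi <- min(dims[ax], max(idx[, ax]) + marginVox[ax])
        as.integer(c(lo, hi))
    })
    box <- new("CropBox", xRange = lohi[[1]], yRange = lohi[[2]],
               zRange = lohi[[3]], marginMm = as.numeric(marginMm))
    slice <- function(a) a[lohi[[1]][1]:lohi[[1]][2],
                           lohi[[2]][1]:lohi[[2]][2],
                           lohi[[3]][1]:lohi[[3]][2], drop = FALSE]
    ctOut <- new("CTVolume", data = slice(ct@data), spacing = ct@spacing,
                 orientation = ct@orientation)
    masksOut <- lapply(masks, function(m)
        new("SegMask", data = slice(m@data), spacing = m@spacing,
            label = m@label))
    list(ct = ctOut, masks = masksOut, box = box)
}

#' Serialize a CropBox for the case report
#'
#' @param box a \code{\linkS4class{CropBox}}.
#' @return A plain list suitable for JSON embedding.
#' @export
cropBoxAsList <- function(box) {
    stopifnot(is(box, "CropBox"))
    list(x_range = box@xRange, y_range = box@yRange, z_range = box@zRange,
         margin_mm = box@marginMm)
}
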