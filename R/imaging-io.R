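## NIfTI input/output.  NIfTI-1/2 (.nii / .nii.gz) is the only on-disk
## format: volumes as int16 or float32, masks as uint8.  No resampling is
## ever performed; masks must sit on the grid of their reference volume.

#' Load a CT volume from NIfTI
#'
#' @param path path to a NIfTI-1/2 file (\code{.nii} or \code{.nii.gz}).
#' @return A \code{\linkS4class{CTVolume}} with spacing taken from the
#'   header pixdims (mm) and the orientation string from the xform.
#' @details Only 3-D images are accepted; a 4-D file (e.g. a time series)
#'   raises a dimensionality error rather than being silently reduced.
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' saveVolume(ctVolume(array(0, c(16, 16, 16)), c(2, 2, 2)), f)
#' dim(imgData(loadVolume(f)))
#' @export
loadVolume <- function(path) {
    if (!file.exists(path))
        stop(sprintf("file not found: %s", path), call. = FALSE)
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 3L)
        stop(sprintf("expected a 3-D image, got %d dimensions (%s)",
                     length(d), paste(d, collapse = "x")), call. = FALSE)
    sp <- RNifti::pixdim(img)[seq_len(3)]
    orient <- tryCatch(RNifti::orientation(img), error = function(e) "RAS")
    ctVolume(array(as.numeric(img), dim = d), spacing = sp,
             orientation = orient)
}

#' Save a CT volume to NIfTI
#'
#' @param x a \code{\linkS4class{CTVolume}}.
#' @param path destination (\code{.nii} or \code{.nii.gz}).
#' @param datatype on-disk type: \code{"float"} (default, lossless for HU
#'   arrays within float precision) or \code{"int16"} (lossless for
#'   integer-valued HU).
#' @return \code{path}, invisibly.
#' @export
saveVolume <- function(x, path, datatype = c("float", "int16")) {
    stopifnot(is(x, "CTVolume"))
    datatype <- match.arg(datatype)
    img <- RNifti::asNifti(x@data)
    RNifti::pixdim(img) <- x@spacing
    current <- tryCatch(RNifti::orientation(img), error = function(e) NA)
    if (!identical(current, x@orientation))
        suppressWarnings(tryCatch(RNifti::orientation(img) <- x@orientation,
                                  error = function(e) NULL))
    RNifti::writeNifti(img, path, datatype = datatype)
    invisible(path)
}

#' Load a segmentation mask from NIfTI
#'
#' @param path path to a NIfTI mask file.
#' @param reference the \code{\linkS4class{CTVolume}} the mask belongs to;
#'   shape and spacing must match exactly (spacing to float32 header
#'   precision) or a grid-mismatch error is raised.
#' @param label provenance label for the mask.
#' @return A \code{\linkS4class{SegMask}}.  Nonzero voxel values are coerced
#'   to 1 with a warning.
#' @export
loadMask <- function(path, reference, label = "reference") {
    if (!file.exists(path))
        stop(sprintf("file not found: %s", path), call. = FALSE)
    stopifnot(is(reference, "CTVolume"))
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 3L)
        stop(sprintf("expected a 3-D mask, got %d dimensions", length(d)),
             call. = FALSE)
    m <- segMask(array(as.numeric(img), dim = d),
                 spacing = RNifti::pixdim(img)[seq_len(3)], label = label)
    if (!.sameGrid(reference, m))
        .stopGridMismatch(reference, m, what = "mask")
    m
}

#' Save a segmentation mask to NIfTI (uint8)
#'
#' @param x a \code{\linkS4class{SegMask}}.
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
saveMask <- function(x, path) {
    stopifnot(is(x, "SegMask"))
    img <- RNifti::asNifti(x@data)
    RNifti::pixdim(img) <- x@spacing
    RNifti::writeNifti(img, path, datatype = "uint8")
    invisible(path)
}

#' Physical volume of one voxel, in millilitres
#'
#' @param spacing numeric(3), voxel edge lengths in mm.
#' @return dx * dy * dz / 1000, the voxel volume in mL.
#' @examples
#' voxelVolumeMl(c(1, 1, 1))   # 0.001
#' voxelVolumeMl(c(2, 2, 2))   # 0.008
#' @export
voxelVolumeMl <- function(spacing) {
    spacing <- as.numeric(spacing)
    if (length(spacing) != 3L || !all(is.finite(spacing)) ||
        any(spacing <= 0))
        stop("spacing must be three strictly positive finite values (mm)",
             call. = FALSE)
    prod(spacing) / 1000
}
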