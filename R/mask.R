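#' Binary segmentation masks
#'
#' A `qam_mask` is one binary voxel grid with its physical voxel spacing and a
#' structure role. Foreground voxels (value 1) belong to the segmented
#' structure. Masks are the elementary input of the whole margin pipeline:
#' tumor, ablation zone and (for subcapsular tumors) the surrounding liver.
#'
#' @param voxels 3-D array coercible to values 0/1 (logical or numeric).
#'   Numeric arrays are thresholded at `> 0.5`, which tolerates masks stored
#'   as floats; any value that is neither background nor foreground after
#'   thresholding must already have been 0/1, otherwise the mask is rejected
#'   as non-binary.
#' @param spacing numeric length-3, voxel edge length in mm per axis (> 0).
#' @param role one of `"tumor"`, `"ablation"`, `"liver"`.
#' @param source_path optional path the mask was read from.
#' @param affine optional 4x4 voxel-to-world matrix, carried through for
#'   output writing only; all computation uses voxel indices and `spacing`.
#'
#' @return An object of class `qam_mask`: list with elements `voxels`
#'   (integer 0/1 array), `shape`, `spacing`, `role`, `source_path`, `affine`.
#' @examples
#' m <- qam_mask(array(c(0, 1), c(2, 2, 2)), spacing = c(1, 1, 2.5),
#'               role = "tumor")
#' sum(m$voxels)
#' @export
qam_mask <- function(voxels, spacing = c(1, 1, 1), role = c("tumor", "ablation", "liver"),
                     source_path = NULL, affine = NULL) {
    role <- match.arg(role)
    if (!is.array(voxels) || length(dim(voxels)) != 3L)
        qam_stop("qam_io_error", "mask voxels must be a 3-D array")
    if (!is.numeric(spacing) || length(spacing) != 3L || any(!is.finite(spacing)) ||
        any(spacing <= 0))
        qam_stop("qam_io_error", "spacing must be three positive lengths in mm")
    v <- as.vector(voxels)
    if (is.logical(v)) {
        if (anyNA(v)) qam_stop("qam_io_error", "mask contains NA voxels")
        vox <- array(as.integer(v), dim(voxels))
    } else {
        if (anyNA(v) || any(!is.finite(v)))
            qam_stop("qam_io_error", "mask contains NA or non-finite voxels")
        # thresholding makes float-stored masks binary, but a genuine label
        # image (values outside {0,1}) violates the binarity contract
        if (any(v != 0 & v != 1))
            qam_stop("qam_binarity_error", sprintf(
                "mask is not binary: values outside {0,1} found (e.g. %g)",
                v[which(v != 0 & v != 1)[1L]]))
        vox <- array(as.integer(v > 0.5), dim(voxels))
    }
    structure(list(voxels = vox, shape = dim(vox), spacing = as.numeric(spacing),
                   role = role, source_path = source_path, affine = affine),
              class = "qam_mask")
}

#' Read a segmentation mask from a NIfTI file
#'
#' Voxel spacing is taken from the image header (`pixdim`); the affine is
#' carried along for later writing. Values are thresholded at `> 0.5`, and a
#' volume containing labels other than 0/1 is rejected.
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @inheritParams qam_mask
#' @return A [qam_mask()].
#' @export
read_mask <- function(path, role = c("tumor", "ablation", "liver")) {
    role <- match.arg(role)
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) qam_stop("qam_io_error", sprintf(
                        "cannot read NIfTI file '%s': %s", path, conditionMessage(e))))
    dm <- dim(img)
    if (length(dm) > 3L) {
        if (any(dm[-(1:3)] != 1L))
            qam_stop("qam_io_error", sprintf("'%s' is not a 3-D volume", path))
        dm <- dm[1:3]
    }
    if (length(dm) != 3L)
        qam_stop("qam_io_error", sprintf("'%s' is not a 3-D volume", path))
    vox <- array(as.numeric(img), dm)
    spacing <- RNifti::pixdim(img)[1:3]
    qam_mask(vox, spacing = spacing, role = role, source_path = path,
             affine = structure(RNifti::xform(img), dimnames = NULL))
}

#' Write a segmentation mask to a NIfTI file
#'
#' The stored affine is used when present; otherwise a diagonal affine built
#' from the voxel spacing.
#'
#' @param mask a [qam_mask()].
#' @param path output file (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
    stopifnot(inherits(mask, "qam_mask"))
    img <- RNifti::asNifti(array(as.integer(mask$voxels), mask$shape))
    RNifti::pixdim(img) <- mask$spacing
    if (!is.null(mask$affine))
        img <- RNifti::`sform<-`(img, structure(mask$affine, code = 2L))
    ok <- tryCatch({ RNifti::writeNifti(img, path); TRUE },
                   error = function(e) FALSE)
    if (!ok) qam_stop("qam_io_error", sprintf("cannot write NIfTI file '%s'", path))
    invisible(path)
}

n_foreground <- function(mask) sum(mask$voxels)

#' @export
print.qam_mask <- function(x, ...) {
    cat(sprintf("<qam_mask> role=%s  grid %s  spacing %s mm  %d foreground voxels\n",
                x$role, paste(x$shape, collapse = "x"),
                paste(format(x$spacing), collapse = "x"), n_foreground(x)))
    invisible(x)
}
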