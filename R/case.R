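#' Assemble a validated ablation case
#'
#' Bundles the tumor and ablation masks (and optionally the surrounding liver
#' mask, needed for subcapsular tumors) of one treated lesion and enforces the
#' registration contract: all masks must share an identical grid and voxel
#' spacing (the package performs no resampling; image fusion is a
#' prerequisite). Tumor and ablation foregrounds must be non-empty.
#'
#' Masks with identical shape and spacing but disagreeing affines are accepted
#' with a warning: computation uses voxel indices and spacing only.
#'
#' @param tumor,ablation [qam_mask()] objects (roles are overridden).
#' @param liver optional [qam_mask()] for the surrounding liver.
#' @param case_id identifier used in reports.
#' @return An object of class `qam_case`.
#' @examples
#' case <- phantom_case_T16()
#' case
#' @export
qam_case <- function(tumor, ablation, liver = NULL, case_id = "case") {
    stopifnot(inherits(tumor, "qam_mask"), inherits(ablation, "qam_mask"))
    tumor$role <- "tumor"; ablation$role <- "ablation"
    masks <- list(tumor = tumor, ablation = ablation)
    if (!is.null(liver)) {
        stopifnot(inherits(liver, "qam_mask"))
        liver$role <- "liver"
        masks$liver <- liver
    }
    ref <- masks[[1L]]
    for (nm in names(masks)[-1L]) {
        m <- masks[[nm]]
        if (!identical(m$shape, ref$shape))
            qam_stop("qam_registration_error", sprintf(
                "grid mismatch: %s is %s but tumor is %s; masks must be co-registered and resampled to one grid",
                nm, paste(m$shape, collapse = "x"), paste(ref$shape, collapse = "x")))
        if (!isTRUE(all.equal(m$spacing, ref$spacing, tolerance = 1e-6)))
            qam_stop("qam_registration_error", sprintf(
                "voxel spacing mismatch: %s has (%s) but tumor has (%s)",
                nm, paste(format(m$spacing), collapse = ", "),
                paste(format(ref$spacing), collapse = ", ")))
        if (!is.null(m$affine) && !is.null(ref$affine) &&
            !isTRUE(all.equal(m$affine, ref$affine, tolerance = 1e-4)))
            qam_warn("qam_affine_warning", sprintf(
                "affine of %s mask differs from tumor mask; computation uses voxel indices and spacing only", nm))
    }
    if (n_foreground(tumor) == 0L)
        qam_stop("qam_empty_structure_error", "tumor mask has empty foreground")
    if (n_foreground(ablation) == 0L)
        qam_stop("qam_empty_structure_error", "ablation mask has empty foreground")
    if (!is.null(liver) && n_foreground(masks$liver) == 0L)
        qam_stop("qam_empty_structure_error", "liver mask has empty foreground")
    structure(list(tumor = masks$tumor, ablation = masks$ablation,
                   liver = masks$liver, case_id = case_id),
              class = "qam_case")
}

#' Read an ablation case from NIfTI files
#'
#' @param tumor_path,ablation_path NIfTI mask files.
#' @param liver_path optional NIfTI liver mask (required for the subcapsular
#'   exclusion algorithm).
#' @param case_id identifier used in reports.
#' @return A [qam_case()].
#' @export
read_case <- function(tumor_path, ablation_path, liver_path = NULL,
                      case_id = "case") {
    qam_case(tumor = read_mask(tumor_path, "tumor"),
             ablation = read_mask(ablation_path, "ablation"),
             liver = if (!is.null(liver_path)) read_mask(liver_path, "liver"),
             case_id = case_id)
}

#' Crop a case to the union bounding box of its structures
#'
#' Optional speed-up: crops all masks to the smallest box containing every
#' foreground voxel of every mask, plus `pad` voxels of background on each
#' side (clipped at the original grid borders). With `pad >= 2` the cropped
#' pipeline output is identical to the uncropped one: surface extraction
#' needs one background layer, and every relevant nearest-surface distance is
#' realized inside the padded box.
#'
#' @param case a [qam_case()].
#' @param pad background margin in voxels (>= 2).
#' @return A cropped [qam_case()].
#' @export
crop_case <- function(case, pad = 2L) {
    stopifnot(inherits(case, "qam_case"))
    if (pad < 2L) qam_stop("qam_io_error", "pad must be >= 2 voxels")
    masks <- Filter(Negate(is.null), list(case$tumor, case$ablation, case$liver))
    lo <- rep(Inf, 3L); hi <- rep(-Inf, 3L)
    for (m in masks) {
        idx <- which(m$voxels == 1L, arr.ind = TRUE)
        lo <- pmin(lo, apply(idx, 2L, min))
        hi <- pmax(hi, apply(idx, 2L, max))
    }
    shape <- case$tumor$shape
    lo <- pmax(1L, as.integer(lo) - as.integer(pad))
    hi <- pmin(shape, as.integer(hi) + as.integer(pad))
    crop1 <- function(m) {
        if (is.null(m)) return(NULL)
        m$voxels <- m$voxels[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L], drop = FALSE]
        m$shape <- dim(m$voxels)
        m
    }
    out <- qam_case(crop1(case$tumor), crop1(case$ablation), crop1(case$liver),
                    case_id = case$case_id)
    out$crop_origin <- lo
    out
}

#' @export
print.qam_case <- function(x, ...) {
    cat(sprintf("<qam_case> '%s'  grid %s  spacing %s mm\n", x$case_id,
                paste(x$tumor$shape, collapse = "x"),
                paste(format(x$tumor$spacing), collapse = "x")))
    cat(sprintf("  tumor: %d voxels | ablation: %d voxels | liver: %s\n",
                n_foreground(x$tumor), n_foreground(x$ablation),
                if (is.null(x$liver)) "absent" else
                    sprintf("%d voxels", n_foreground(x$liver))))
    invisible(x)
}
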