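#' Exact Euclidean distance transform of a voxel set
#'
#' For every voxel of the grid, the exact (not chamfer) Euclidean distance
#' from its center to the nearest voxel center of `zero_set`, honoring
#' anisotropic voxel spacing. Implemented as the separable lower-envelope
#' transform on squared distances, which is exact for weighted squared
#' Euclidean metrics.
#'
#' @param zero_set logical 3-D array marking the zero-distance voxels.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @param squared return squared distances (mm^2) instead of distances (mm).
#' @return numeric 3-D array of distances in mm (or mm^2).
#' @export
distance_transform <- function(zero_set, spacing = c(1, 1, 1), squared = FALSE) {
    stopifnot(is.logical(zero_set), length(dim(zero_set)) == 3L)
    if (!any(zero_set))
        qam_stop("qam_empty_structure_error", "distance transform of an empty zero set")
    d2 <- .edt_sq(zero_set, as.numeric(spacing))
    if (squared) d2 else sqrt(d2)
}

#' Signed Euclidean distance map of the ablation zone
#'
#' Builds the per-voxel signed distance map (mm) against which tumor-surface
#' margins are read off. Voxels outside the ablation foreground always carry
#' the negative distance to the nearest ablation voxel (equivalently, to the
#' nearest ablation-surface voxel). For voxels inside the ablation two
#' conventions are supported:
#'
#' * `interior = "surface"` (default): distance to the nearest
#'   ablation-surface voxel (contour of the mask, via [extract_surface()]).
#'   Surface voxels map to exactly 0, so coincident tumor and ablation
#'   surfaces yield zero margins, and every margin equals the all-pairs
#'   surface-to-surface minimum distance.
#' * `interior = "background"`: distance to the nearest non-ablated voxel
#'   (the classic signed distance transform). Interior margins then measure
#'   the depth of necrotic tissue between the tumor boundary and non-ablated
#'   tissue; contour voxels map to one voxel step rather than 0. This is the
#'   convention under which the published sphere-phantom reference tables of
#'   this metric are reproduced (see the package vignette).
#'
#' @param ablation a [qam_mask()] with role `"ablation"` (non-empty).
#' @param interior interior distance convention, see Details.
#' @return An object of class `qam_sdm`: list with `values` (3-D array, mm;
#'   negative outside the ablation), `spacing`, `interior`.
#' @export
signed_distance_map <- function(ablation, interior = c("surface", "background")) {
    stopifnot(inherits(ablation, "qam_mask"))
    interior <- match.arg(interior)
    fg <- ablation$voxels == 1L
    if (!any(fg))
        qam_stop("qam_empty_structure_error", "ablation mask has empty foreground")
    sp <- ablation$spacing
    if (interior == "surface") {
        d <- sqrt(.edt_sq(surface_array(fg), sp))
        vals <- ifelse(fg, d, -d)
    } else {
        if (all(fg))
            qam_stop("qam_empty_structure_error",
                     "ablation fills the whole grid: no background for the signed map")
        d_in <- sqrt(.edt_sq(!fg, sp))   # inside: distance to nearest background
        d_out <- sqrt(.edt_sq(fg, sp))   # outside: distance to nearest foreground
        vals <- ifelse(fg, d_in, -d_out)
    }
    structure(list(values = vals, spacing = sp, interior = interior),
              class = "qam_sdm")
}

#' Subcapsular exclusion of tumor-surface voxels
#'
#' For subcapsular tumors a full circumferential margin is physically
#' impossible, so tumor-surface voxels strictly closer than `threshold` mm to
#' the liver surface are excluded from the margin distribution (they are
#' removed from the denominator, not set to margin zero). The threshold
#' defaults to the 5 mm minimal-margin convention but can be adapted to the
#' treatment target.
#'
#' Distances to the liver surface follow the same convention as the ablation
#' map: with `interior = "surface"` the distance to the liver contour
#' ([extract_surface()]); with `"background"` the distance to the nearest
#' non-liver voxel. Tumor-surface voxels outside the liver foreground trigger
#' a warning (and are excluded at any positive threshold under
#' `"background"`, where their distance is taken as 0).
#'
#' @param tumor_surface a `qam_surface` of the tumor.
#' @param liver a liver [qam_mask()] (non-empty).
#' @param threshold exclusion distance in mm (strict `<`); 0 excludes nothing.
#' @param interior distance convention, see [signed_distance_map()].
#' @return list with `included` (a `qam_surface`), `excluded` (m x 3 integer
#'   index matrix) and `liver_distance` (per-surface-voxel distances, mm, in
#'   the original surface order).
#' @export
exclude_subcapsular <- function(tumor_surface, liver, threshold = 5,
                                interior = c("surface", "background")) {
    stopifnot(inherits(tumor_surface, "qam_surface"), inherits(liver, "qam_mask"))
    interior <- match.arg(interior)
    if (!isTRUE(all.equal(tumor_surface$parent_spacing, liver$spacing)) ||
        !identical(tumor_surface$parent_shape, liver$shape))
        qam_stop("qam_registration_error",
                 "tumor surface and liver mask are on different grids")
    fg <- liver$voxels == 1L
    if (!any(fg))
        qam_stop("qam_empty_structure_error", "liver mask has empty foreground")
    sp <- liver$spacing
    idx <- tumor_surface$indices
    inside <- fg[idx]
    if (!all(inside))
        qam_warn("qam_subcapsular_warning", sprintf(
            "%d tumor-surface voxels lie outside the liver foreground; liver segmentation should extend at least %g mm beyond the tumor",
            sum(!inside), threshold))
    if (interior == "surface") {
        d <- sqrt(.edt_sq(surface_array(fg), sp))[idx]
    } else {
        d <- sqrt(.edt_sq(!fg, sp))
        d <- ifelse(fg, d, 0)[idx]
    }
    excl <- d < threshold
    if (all(excl))
        qam_stop("qam_all_excluded_error", sprintf(
            "all %d tumor-surface voxels lie within %g mm of the liver surface; for such small subcapsular tumors every voxel is subtracted and no surface distances can be yielded",
            length(excl), threshold))
    included <- tumor_surface
    included$indices <- idx[!excl, , drop = FALSE]
    list(included = included,
         excluded = idx[excl, , drop = FALSE],
         liver_distance = d)
}
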