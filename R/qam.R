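#' Quantitative ablation margins for one treated tumor
#'
#' The main entry point. Takes one ablation case (either a [qam_case()] or
#' the tumor/ablation/liver masks or NIfTI paths), optionally crops to the
#' union bounding box of the structures, computes the signed exact Euclidean
#' surface margins of the tumor against the ablation zone and, for
#' subcapsular tumors, applies the liver-capsule exclusion. The result is a
#' classed object with `print`, `summary` and `plot` methods.
#'
#' @param tumor a [qam_case()], a tumor [qam_mask()], or a NIfTI path.
#' @param ablation ablation [qam_mask()] or NIfTI path (ignored when `tumor`
#'   is a `qam_case`).
#' @param liver optional liver [qam_mask()] or NIfTI path.
#' @param case_id identifier used in reports.
#' @param subcapsular apply the subcapsular exclusion algorithm (requires a
#'   liver mask). Default `FALSE`.
#' @param exclusion_threshold exclusion distance below the liver capsule in
#'   mm (strict `<`); default 5 mm, the accepted minimal-margin convention.
#' @param interior interior distance convention of the signed map, see
#'   [signed_distance_map()].
#' @param crop crop all masks to the union bounding box before computing
#'   (identical results, less memory/time). Default `TRUE`.
#' @param pad background padding of the crop in voxels (>= 2).
#' @return An object of class `qam`: the margin distribution
#'   (`$margins`, mm, one value per included tumor-surface voxel), the
#'   included surface and excluded voxel set, and the case. Methods:
#'   [summary.qam()], [plot.qam()], [project_margins()].
#' @examples
#' fit <- qam(phantom_case_T16())
#' fit
#' summary(fit)
#' @export
qam <- function(tumor, ablation = NULL, liver = NULL, case_id = "case",
                subcapsular = FALSE, exclusion_threshold = 5,
                interior = c("surface", "background"),
                crop = TRUE, pad = 2L) {
    interior <- match.arg(interior)
    case <- if (inherits(tumor, "qam_case")) {
        tumor
    } else {
        as_mask <- function(x, role) {
            if (is.null(x)) return(NULL)
            if (inherits(x, "qam_mask")) { x$role <- role; x }
            else read_mask(x, role)
        }
        qam_case(as_mask(tumor, "tumor"), as_mask(ablation, "ablation"),
                 as_mask(liver, "liver"), case_id = case_id)
    }
    full <- case
    if (crop) case <- crop_case(case, pad = pad)
    md <- compute_margins(case, use_exclusion = subcapsular,
                          exclusion_threshold = exclusion_threshold,
                          interior = interior)
    structure(list(margins = md$margins, included = md$included,
                   excluded = md$excluded,
                   exclusion_threshold = md$exclusion_threshold,
                   subcapsular = subcapsular, interior = interior,
                   spacing = case$tumor$spacing, case = case,
                   case_id = full$case_id,
                   crop_origin = if (crop) case$crop_origin else c(1L, 1L, 1L)),
              class = "qam")
}

#' @export
print.qam <- function(x, digits = 2, ...) {
    cat(sprintf("Quantitative ablation margins for case '%s'\n", x$case_id))
    cat(sprintf("  tumor surface voxels: %d included, %d excluded%s\n",
                length(x$margins), nrow(x$excluded),
                if (x$subcapsular) sprintf(" (subcapsular exclusion < %g mm)",
                                           x$exclusion_threshold) else ""))
    q <- stats::quantile(x$margins, c(0, .25, .5, .75, 1), names = FALSE, type = 7)
    cat(sprintf("  margin [mm]: min %.*f | p25 %.*f | median %.*f | p75 %.*f | max %.*f\n",
                digits, q[1], digits, q[2], digits, q[3], digits, q[4], digits, q[5]))
    cf <- class_fractions(x$margins)
    cat(sprintf("  coverage: x<0: %.2f%% | 0<=x<5: %.2f%% | x>=5: %.2f%%\n",
                cf[1], cf[2], cf[3]))
    invisible(x)
}
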