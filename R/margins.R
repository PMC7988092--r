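#' Signed surface margins of a case
#'
#' The core computation: the signed ablation distance map
#' ([signed_distance_map()]) sampled at every tumor-surface voxel, after the
#' optional subcapsular exclusion. Margins are in mm; a negative margin means
#' the tumor-surface voxel is not covered by the ablation.
#'
#' @param case a [qam_case()].
#' @param use_exclusion apply the subcapsular exclusion (requires a liver
#'   mask in the case).
#' @param exclusion_threshold exclusion distance in mm, strict `<`.
#' @param interior interior distance convention, see [signed_distance_map()].
#' @return An object of class `qam_margins`: list with `margins` (numeric
#'   vector, one per included tumor-surface voxel), `included`
#'   (`qam_surface`), `excluded` (index matrix), `exclusion_threshold`,
#'   `interior`, `spacing`.
#' @export
compute_margins <- function(case, use_exclusion = FALSE, exclusion_threshold = 5,
                            interior = c("surface", "background")) {
    stopifnot(inherits(case, "qam_case"))
    interior <- match.arg(interior)
    tsurf <- extract_surface(case$tumor)
    excluded <- matrix(integer(0), 0L, 3L)
    if (use_exclusion) {
        if (is.null(case$liver))
            qam_stop("qam_missing_liver_error",
                     "subcapsular exclusion requested but the case has no liver mask")
        ex <- exclude_subcapsular(tsurf, case$liver, threshold = exclusion_threshold,
                                  interior = interior)
        tsurf <- ex$included
        excluded <- ex$excluded
    }
    sdm <- signed_distance_map(case$ablation, interior = interior)
    structure(list(margins = sdm$values[tsurf$indices],
                   included = tsurf, excluded = excluded,
                   exclusion_threshold = if (use_exclusion) exclusion_threshold else NA_real_,
                   interior = interior, spacing = case$tumor$spacing,
                   case_id = case$case_id),
              class = "qam_margins")
}

#' @export
print.qam_margins <- function(x, ...) {
    cat(sprintf("<qam_margins> '%s'  %d included, %d excluded tumor-surface voxels\n",
                x$case_id, length(x$margins), nrow(x$excluded)))
    cat(sprintf("  margins [mm]: min %.2f | median %.2f | max %.2f\n",
                min(x$margins), stats::median(x$margins), max(x$margins)))
    invisible(x)
}
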