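#' Run the full QAM pipeline for one case and write all outputs
#'
#' Executes load -> crop -> margins (with optional subcapsular exclusion) ->
#' summary -> histogram -> surface mesh, and writes four files into
#' `output_dir`: `<case>_summary.json`, `<case>_distances.csv`,
#' `<case>_histogram.png` and `<case>_surface.vtk`. Voxel counts, exclusion
#' counts and the distance summary are logged at case granularity. Outputs
#' are deterministic for fixed inputs and configuration.
#'
#' @param tumor,ablation,liver NIfTI paths or [qam_mask()] objects (liver
#'   optional).
#' @param output_dir output directory (created if needed).
#' @param case_id identifier used in file names and reports.
#' @param subcapsular apply the subcapsular exclusion (requires `liver`).
#' @param exclusion_threshold exclusion distance in mm.
#' @param class_low,class_high traffic-light class bounds in mm.
#' @param bin_width histogram substrata width in mm.
#' @param percentile_method see [summary.qam()].
#' @param interior see [signed_distance_map()].
#' @param pad crop padding in voxels.
#' @param quiet suppress log messages.
#' @return invisibly, a list with the `qam` fit, its summary and the output
#'   file paths.
#' @export
run_qam <- function(tumor, ablation, liver = NULL, output_dir = ".",
                    case_id = "case", subcapsular = FALSE,
                    exclusion_threshold = 5, class_low = 0, class_high = 5,
                    bin_width = 1, percentile_method = "linear",
                    interior = "surface", pad = 2L, quiet = FALSE) {
    t0 <- proc.time()[["elapsed"]]
    if (!dir.exists(output_dir) &&
        !dir.create(output_dir, recursive = TRUE, showWarnings = FALSE))
        qam_stop("qam_io_error", sprintf("cannot create output directory '%s'", output_dir))
    fit <- qam(tumor, ablation, liver, case_id = case_id,
               subcapsular = subcapsular,
               exclusion_threshold = exclusion_threshold,
               interior = interior, pad = pad)
    s <- summary(fit, low = class_low, high = class_high, bin_width = bin_width,
                 percentile_method = percentile_method)
    stem <- file.path(output_dir, gsub("[^A-Za-z0-9._-]", "_", case_id))
    paths <- list(summary = paste0(stem, "_summary.json"),
                  distances = paste0(stem, "_distances.csv"),
                  histogram = paste0(stem, "_histogram.png"),
                  surface = paste0(stem, "_surface.vtk"))
    write_qam_summary(s, paths$summary)
    write_qam_distances(fit, paths$distances)
    save_qam_histogram(s, paths$histogram)
    write_surface_vtk(project_margins(fit, low = class_low, high = class_high),
                      paths$surface)
    if (!quiet) {
        message(sprintf(
            "[%s] %d tumor-surface voxels (%d excluded); margin min/median/max = %.2f/%.2f/%.2f mm",
            case_id, s$n_included + s$n_excluded, s$n_excluded,
            s$min, s$median, s$max))
        message(sprintf(
            "[%s] coverage x<%g: %.2f%% | %g<=x<%g: %.2f%% | x>=%g: %.2f%% | %.1f s",
            case_id, class_low, s$class_fractions[1L], class_low, class_high,
            s$class_fractions[2L], class_high, s$class_fractions[3L],
            proc.time()[["elapsed"]] - t0))
    }
    invisible(list(fit = fit, summary = s, paths = paths))
}

#' Write a named phantom case as NIfTI files
#'
#' Emits the reference sphere phantoms (`"T1.6"`, `"T2.2"`) as NIfTI mask
#' triplets (tumor/ablation, plus liver for subcapsular cases) for use as
#' pipeline inputs.
#'
#' @param which `"T1.6"`, `"T2.2"` or `"all"`.
#' @param output_dir output directory (created if needed).
#' @return invisibly, character vector of written files.
#' @export
generate_phantoms <- function(which = "all", output_dir = ".") {
    known <- c("T1.6", "T2.2")
    which <- if (identical(which, "all")) known else which
    if (!all(which %in% known))
        qam_stop("qam_io_error", sprintf(
            "unknown phantom case '%s' (known: %s)",
            setdiff(which, known)[1L], paste(known, collapse = ", ")))
    if (!dir.exists(output_dir) &&
        !dir.create(output_dir, recursive = TRUE, showWarnings = FALSE))
        qam_stop("qam_io_error", sprintf("cannot create output directory '%s'", output_dir))
    out <- character(0)
    for (w in which) {
        case <- if (w == "T1.6") phantom_case_T16() else phantom_case_T22()
        stem <- file.path(output_dir, gsub(".", "", w, fixed = TRUE))
        for (role in c("tumor", "ablation", "liver")) {
            if (is.null(case[[role]])) next
            p <- sprintf("%s_%s.nii.gz", stem, role)
            write_mask(case[[role]], p)
            out <- c(out, p)
        }
    }
    invisible(out)
}
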