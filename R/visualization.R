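#' Project margins onto the ablation surface
#'
#' For 3-D review, every ablation-surface voxel is assigned the signed margin
#' of its nearest included tumor-surface voxel (Euclidean, spacing-aware);
#' ties are broken by the smallest (most pessimistic) margin, so uncovered
#' tumor regions always show through. This definition makes orange regions on
#' the ablation surface correspond to actually uncovered tumor surface.
#'
#' @param fit a [qam()] fit.
#' @param low,high traffic-light class bounds in mm.
#' @return An object of class `qam_surface_map`: list with `vertices`
#'   (n x 3 matrix, mm positions of ablation-surface voxel centers),
#'   `scalar` (signed margin, mm) and `class` (factor orange/yellow/green).
#' @export
project_margins <- function(fit, low = 0, high = 5) {
    stopifnot(inherits(fit, "qam"))
    if (length(fit$margins) == 0L)
        qam_stop("qam_all_excluded_error", "no included tumor-surface voxels to project")
    asurf <- extract_surface(fit$case$ablation)
    sp <- fit$spacing
    av <- sweep(asurf$indices - 1, 2L, sp, `*`)
    tv <- sweep(fit$included$indices - 1, 2L, sp, `*`)
    n <- nrow(av)
    scalar <- numeric(n)
    # chunked nearest-neighbor search with pessimistic tie-break
    step <- max(1L, floor(2e6 / max(1L, nrow(tv))))
    for (s in seq(1L, n, by = step)) {
        e <- min(n, s + step - 1L)
        block <- av[s:e, , drop = FALSE]
        d2 <- outer(rowSums(block^2), rowSums(tv^2), `+`) -
            2 * tcrossprod(block, tv)
        scalar[s:e] <- vapply(seq_len(nrow(block)), function(r) {
            dr <- d2[r, ]
            ties <- which(dr <= min(dr) + 1e-9)
            min(fit$margins[ties])
        }, numeric(1L))
    }
    structure(list(vertices = av, scalar = scalar,
                   class = classify_margin(scalar, low, high),
                   case_id = fit$case_id),
              class = "qam_surface_map")
}

#' Write a colored ablation surface as VTK polydata
#'
#' Legacy ASCII VTK polydata with one vertex per ablation-surface voxel and
#' two point-data fields: `qam_mm` (signed margin, mm) and `qam_class`
#' (0 = orange, 1 = yellow, 2 = green), for viewing in standard 3-D viewers.
#'
#' @param cmap a [project_margins()] surface map.
#' @param path output `.vtk` file.
#' @return `path`, invisibly.
#' @export
write_surface_vtk <- function(cmap, path) {
    stopifnot(inherits(cmap, "qam_surface_map"))
    n <- nrow(cmap$vertices)
    con <- tryCatch(file(path, "w"),
                    error = function(e) qam_stop("qam_io_error", sprintf(
                        "cannot open '%s' for writing", path)))
    on.exit(close(con))
    writeLines(c("# vtk DataFile Version 3.0",
                 sprintf("QAM ablation surface (%s)", cmap$case_id),
                 "ASCII", "DATASET POLYDATA",
                 sprintf("POINTS %d float", n)), con)
    writeLines(apply(format(cmap$vertices, trim = TRUE, digits = 9), 1L,
                     paste, collapse = " "), con)
    writeLines(sprintf("VERTICES %d %d", n, 2L * n), con)
    writeLines(sprintf("1 %d", seq_len(n) - 1L), con)
    writeLines(c(sprintf("POINT_DATA %d", n),
                 "SCALARS qam_mm float 1", "LOOKUP_TABLE default"), con)
    writeLines(format(cmap$scalar, trim = TRUE, digits = 9), con)
    writeLines(c("SCALARS qam_class int 1", "LOOKUP_TABLE default"), con)
    writeLines(as.character(as.integer(cmap$class) - 1L), con)
    invisible(path)
}

qam_class_colors <- c(orange = "#E69F00", yellow = "#F0E442", green = "#009E73")

#' Traffic-light histogram of margin substrata
#'
#' Bar chart of the relative margin distribution in substrata bins, each bar
#' colored by the traffic-light class of its bin center. `plot.qam` computes
#' the summary first; `plot.summary.qam` plots an existing summary.
#'
#' @param x a [qam()] fit or [summary.qam()] object.
#' @param main plot title.
#' @param ... for `plot.qam`, passed to [summary.qam()].
#' @return the summary, invisibly.
#' @export
plot.qam <- function(x, main = NULL, ...) {
    plot(summary(x, ...), main = main)
}

#' @rdname plot.qam
#' @export
plot.summary.qam <- function(x, main = NULL, ...) {
    bins <- x$bins
    centers <- seq(min(bins$center), max(bins$center), by = x$bin_width)
    pct <- stats::setNames(numeric(length(centers)), centers)
    pct[as.character(bins$center)] <- bins$percent
    cols <- qam_class_colors[as.character(classify_margin(centers,
                                                          x$threshold_low,
                                                          x$threshold_high))]
    graphics::barplot(pct, names.arg = centers, col = cols, border = NA,
                      xlab = "Ablation margin [mm]",
                      ylab = "Tumor surface [%]",
                      main = main %||% sprintf("QAM distribution: %s", x$case_id))
    graphics::legend("topright", bty = "n", fill = qam_class_colors,
                     legend = c(sprintf("x < %g mm", x$threshold_low),
                                sprintf("%g <= x < %g mm", x$threshold_low,
                                        x$threshold_high),
                                sprintf("x >= %g mm", x$threshold_high)))
    invisible(x)
}

#' Save the traffic-light histogram as PNG
#'
#' @param summary a [summary.qam()] object.
#' @param path output PNG file.
#' @param width,height,res device settings.
#' @return `path`, invisibly.
#' @export
save_qam_histogram <- function(summary, path, width = 1200, height = 800,
                               res = 150) {
    ok <- tryCatch({
        grDevices::png(path, width = width, height = height, res = res)
        on.exit(grDevices::dev.off())
        plot(summary)
        TRUE
    }, error = function(e) FALSE)
    if (!ok || !file.exists(path))
        qam_stop("qam_io_error", sprintf("cannot write histogram to '%s'", path))
    invisible(path)
}
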