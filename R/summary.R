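#' Traffic-light margin classes
#'
#' Margins are classified into the three clinically used coverage classes:
#' `orange` (x < low mm, uncovered tumor surface), `yellow`
#' (low <= x < high mm, covered with insufficient margin) and `green`
#' (x >= high mm, covered with sufficient margin). Defaults `low = 0`,
#' `high = 5` follow the accepted 5 mm minimal-margin definition; both bounds
#' are configurable.
#'
#' @param margin numeric vector of signed margins in mm.
#' @param low,high class boundaries in mm, `low < high`.
#' @return factor with levels `orange`, `yellow`, `green`.
#' @examples
#' classify_margin(c(-0.5, 0, 4.9, 5))
#' @export
classify_margin <- function(margin, low = 0, high = 5) {
    if (!is.numeric(low) || !is.numeric(high) || !is.finite(low) ||
        !is.finite(high) || low >= high)
        qam_stop("qam_io_error", "class bounds must satisfy low < high")
    factor(ifelse(margin < low, "orange", ifelse(margin < high, "yellow", "green")),
           levels = c("orange", "yellow", "green"))
}

class_fractions <- function(margins, low = 0, high = 5) {
    cl <- classify_margin(margins, low, high)
    100 * as.numeric(table(cl)) / length(margins)
}

# integer-centred 1 mm-substrata bin of a margin: bin k covers [k-0.5, k+0.5)
margin_bin <- function(margin, width = 1) width * floor(margin / width + 0.5)

#' Summarize a margin distribution
#'
#' Numerical report of a [qam()] fit: minimum, quartiles and maximum of the
#' signed margins, traffic-light class fractions, and the substrata histogram
#' in bins of `bin_width` mm centered on integer multiples of the width
#' (bin k covers `[k - w/2, k + w/2)`). Class fractions are always computed
#' from the raw margins, never from the bins; excluded subcapsular voxels are
#' removed from the denominator.
#'
#' @param object a [qam()] fit (or a `qam_margins` object).
#' @param low,high traffic-light class bounds in mm.
#' @param bin_width histogram substrata width in mm.
#' @param percentile_method `"linear"` (interpolation between closest ranks,
#'   the default) or `"nearest"` (inverse-CDF nearest rank).
#' @param quantize_mm if non-`NULL`, percentiles and extrema are computed on
#'   margins quantized to this reporting resolution (the substrata bin
#'   centers); the published phantom reference tables report distance
#'   summaries at the 1 mm histogram resolution. Class fractions are always
#'   computed on raw margins.
#' @param ... unused.
#' @return An object of class `summary.qam` with fields `min`, `p25`,
#'   `median`, `p75`, `max`, `class_fractions` (percent, named
#'   orange/yellow/green), `bins` (data.frame: `center`, `percent`, `class`),
#'   `n_included`, `n_excluded`, `threshold_low`, `threshold_high`.
#' @export
summary.qam <- function(object, low = 0, high = 5, bin_width = 1,
                        percentile_method = c("linear", "nearest"),
                        quantize_mm = NULL, ...) {
    percentile_method <- match.arg(percentile_method)
    m <- object$margins
    if (length(m) == 0L)
        qam_stop("qam_all_excluded_error", "margin distribution is empty")
    type <- if (percentile_method == "linear") 7L else 1L
    mq <- if (is.null(quantize_mm)) m else margin_bin(m, quantize_mm)
    q <- stats::quantile(mq, c(.25, .5, .75), names = FALSE, type = type)
    cf <- class_fractions(m, low, high)
    centers <- margin_bin(m, bin_width)
    tab <- table(centers)
    bins <- data.frame(center = as.numeric(names(tab)),
                       percent = 100 * as.numeric(tab) / length(m))
    bins$class <- classify_margin(bins$center, low, high)
    structure(list(case_id = object$case_id %||% "case",
                   min = min(mq), p25 = q[1L], median = q[2L], p75 = q[3L],
                   max = max(mq),
                   class_fractions = c(orange = cf[1L], yellow = cf[2L], green = cf[3L]),
                   bins = bins,
                   n_included = length(m), n_excluded = nrow(object$excluded),
                   threshold_low = low, threshold_high = high,
                   bin_width = bin_width,
                   percentile_method = percentile_method,
                   quantize_mm = quantize_mm),
              class = "summary.qam")
}

#' @export
summary.qam_margins <- summary.qam

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.summary.qam <- function(x, ...) {
    cat(sprintf("QAM summary for case '%s' (n = %d included, %d excluded)\n",
                x$case_id, x$n_included, x$n_excluded))
    cat("  Euclidean distance [mm]      Tumor surface covered at distance\n")
    lab <- sprintf("x < %g", x$threshold_low)
    lab2 <- sprintf("%g <= x < %g", x$threshold_low, x$threshold_high)
    lab3 <- sprintf("x >= %g", x$threshold_high)
    rows <- cbind(c("Min", "25th percentile", "Median", "75th percentile", "Max"),
                  sprintf("%.2f", c(x$min, x$p25, x$median, x$p75, x$max)),
                  c(lab, lab2, lab3, "", ""),
                  c(sprintf("%.2f%%", x$class_fractions), "", ""))
    for (i in seq_len(nrow(rows)))
        cat(sprintf("  %-16s %8s     %-12s %s\n", rows[i, 1], rows[i, 2],
                    rows[i, 3], rows[i, 4]))
    invisible(x)
}

#' Write a QAM summary as JSON
#'
#' Machine-readable record mirroring the numerical report: distance summary,
#' class fractions, substrata histogram and voxel counts.
#'
#' @param summary a [summary.qam()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qam_summary <- function(summary, path) {
    stopifnot(inherits(summary, "summary.qam"))
    rec <- list(case_id = summary$case_id,
                distances_mm = list(min = summary$min, p25 = summary$p25,
                                    median = summary$median, p75 = summary$p75,
                                    max = summary$max),
                class_fractions_percent = as.list(summary$class_fractions),
                class_bounds_mm = c(summary$threshold_low, summary$threshold_high),
                bins = summary$bins[, c("center", "percent")],
                n_included = summary$n_included,
                n_excluded = summary$n_excluded)
    ok <- tryCatch({
        jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
        TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok || !file.exists(path))
        qam_stop("qam_io_error", sprintf("cannot write summary to '%s'", path))
    invisible(path)
}

#' Write per-voxel margins as CSV
#'
#' One row per tumor-surface voxel: 0-based voxel index `i,j,k`, the signed
#' margin in mm for included voxels, and an `excluded` flag. Excluded
#' (subcapsular) voxels carry no margin value.
#'
#' @param x a [qam()] fit.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_qam_distances <- function(x, path) {
    stopifnot(inherits(x, "qam") || inherits(x, "qam_margins"))
    inc <- x$included$indices
    exc <- x$excluded
    df <- data.frame(i = c(inc[, 1L], exc[, 1L]) - 1L,
                     j = c(inc[, 2L], exc[, 2L]) - 1L,
                     k = c(inc[, 3L], exc[, 3L]) - 1L,
                     margin_mm = c(x$margins, rep(NA_real_, nrow(exc))),
                     excluded = rep(c(FALSE, TRUE), c(nrow(inc), nrow(exc))))
    ok <- tryCatch({ utils::write.csv(df, path, row.names = FALSE, na = ""); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok || !file.exists(path))
        qam_stop("qam_io_error", sprintf("cannot write distances to '%s'", path))
    invisible(path)
}
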