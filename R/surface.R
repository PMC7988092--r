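#' Face-connected surface voxels of a mask
#'
#' The surface (contour) of a binary mask is the mask minus its morphological
#' erosion by the 6-connectivity (face-adjacency) structuring element: a
#' foreground voxel survives erosion only if all six face neighbors are
#' foreground, with everything outside the grid counting as background. This
#' yields a one-voxel-thin contour that retains corners along sharp edges.
#'
#' @param mask a [qam_mask()] with non-empty foreground.
#' @return An object of class `qam_surface`: list with `indices` (n x 3
#'   integer matrix of 1-based voxel indices), `parent_shape`,
#'   `parent_spacing`, `role`.
#' @examples
#' cube <- array(0L, c(7, 7, 7)); cube[3:5, 3:5, 3:5] <- 1L
#' s <- extract_surface(qam_mask(cube, role = "tumor"))
#' nrow(s$indices)  # 26: all cube voxels except the centre
#' @export
extract_surface <- function(mask) {
    stopifnot(inherits(mask, "qam_mask"))
    if (n_foreground(mask) == 0L)
        qam_stop("qam_empty_structure_error",
                 sprintf("%s mask has empty foreground", mask$role))
    surf <- surface_array(mask$voxels == 1L)
    structure(list(indices = which(surf, arr.ind = TRUE, useNames = FALSE),
                   parent_shape = mask$shape, parent_spacing = mask$spacing,
                   role = mask$role),
              class = "qam_surface")
}

# logical surface array: mask minus its 6-connected erosion
surface_array <- function(fg) {
    er <- erode6(fg)
    fg & !er
}

# erosion by the 3x3x3 face-connectivity cross; out-of-grid = background
erode6 <- function(fg) {
    d <- dim(fg)
    er <- fg
    shift_and <- function(er, axis, by) {
        n <- d[axis]
        if (axis == 1L) {
            nb <- fg[c(seq_len(n)[-1L], n), , , drop = FALSE]
            if (by == -1L) nb <- fg[c(1L, seq_len(n - 1L)), , , drop = FALSE]
            if (by == +1L) nb[n, , ] <- FALSE else nb[1L, , ] <- FALSE
        } else if (axis == 2L) {
            nb <- fg[, c(seq_len(n)[-1L], n), , drop = FALSE]
            if (by == -1L) nb <- fg[, c(1L, seq_len(n - 1L)), , drop = FALSE]
            if (by == +1L) nb[, n, ] <- FALSE else nb[, 1L, ] <- FALSE
        } else {
            nb <- fg[, , c(seq_len(n)[-1L], n), drop = FALSE]
            if (by == -1L) nb <- fg[, , c(1L, seq_len(n - 1L)), drop = FALSE]
            if (by == +1L) nb[, , n] <- FALSE else nb[, , 1L] <- FALSE
        }
        er & nb
    }
    for (axis in 1:3) {
        er <- shift_and(er, axis, +1L)  # neighbor at index+1
        er <- shift_and(er, axis, -1L)  # neighbor at index-1
    }
    er
}

#' @export
print.qam_surface <- function(x, ...) {
    cat(sprintf("<qam_surface> role=%s  %d surface voxels on grid %s\n",
                x$role, nrow(x$indices), paste(x$parent_shape, collapse = "x")))
    invisible(x)
}
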