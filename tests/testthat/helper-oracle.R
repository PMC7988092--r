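# Independent brute-force oracles. These deliberately avoid the package's
# erosion / distance-transform code paths: surfaces come from an explicit
# neighbor scan, distances from all-pairs minima.

# voxel indices (n x 3) whose 6-neighborhood touches background or the border
oracle_surface <- function(vox) {
    d <- dim(vox)
    idx <- which(vox == 1L, arr.ind = TRUE, useNames = FALSE)
    keep <- vapply(seq_len(nrow(idx)), function(r) {
        p <- idx[r, ]
        for (a in 1:3) for (s in c(-1L, 1L)) {
            q <- p; q[a] <- q[a] + s
            if (q[a] < 1L || q[a] > d[a]) return(TRUE)
            if (vox[q[1L], q[2L], q[3L]] == 0L) return(TRUE)
        }
        FALSE
    }, logical(1L))
    idx[keep, , drop = FALSE]
}

# all-pairs minimum distances from each row of `from` (n x 3 voxel indices)
# to the voxel set `to`; accumulation order matches the separable transform
# so exact agreement can be asserted under dyadic spacings
oracle_min_dist <- function(from, to, spacing) {
    w2 <- spacing * spacing
    d2 <- w2[1L] * outer(from[, 1L], to[, 1L], `-`)^2 +
          w2[2L] * outer(from[, 2L], to[, 2L], `-`)^2 +
          w2[3L] * outer(from[, 3L], to[, 3L], `-`)^2
    sqrt(apply(d2, 1L, min))
}

# signed surface margins by brute force
oracle_margins <- function(case, interior = "surface") {
    tvox <- case$tumor$voxels
    avox <- case$ablation$voxels
    sp <- case$tumor$spacing
    ts <- oracle_surface(tvox)
    inside <- avox[ts] == 1L
    if (interior == "surface") {
        as_surf <- oracle_surface(avox)
        d <- oracle_min_dist(ts, as_surf, sp)
    } else {
        fg_idx <- which(avox == 1L, arr.ind = TRUE, useNames = FALSE)
        bg_idx <- which(avox == 0L, arr.ind = TRUE, useNames = FALSE)
        d <- numeric(nrow(ts))
        if (any(inside))
            d[inside] <- oracle_min_dist(ts[inside, , drop = FALSE], bg_idx, sp)
        if (any(!inside))
            d[!inside] <- oracle_min_dist(ts[!inside, , drop = FALSE], fg_idx, sp)
    }
    ifelse(inside, d, -d)
}

sort_rows <- function(m) m[order(m[, 1L], m[, 2L], m[, 3L]), , drop = FALSE]

# order-free comparison of two margin multisets
expect_same_multiset <- function(a, b, tolerance = NULL) {
    if (is.null(tolerance)) expect_identical(sort(a), sort(b))
    else expect_equal(sort(a), sort(b), tolerance = tolerance)
}

# dyadic voxel spacings typical of CT, exact in binary floating point
dyadic_spacings <- list(c(1, 1, 1), c(0.5, 0.5, 0.5), c(1, 1, 2.5),
                        c(0.75, 0.75, 3), c(1.25, 0.5, 2.5))

# small solid cuboid mask helper
cuboid_mask <- function(shape, lo, hi, spacing = c(1, 1, 1), role = "tumor") {
    v <- array(0L, shape)
    v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1L
    qam_mask(v, spacing = spacing, role = role)
}

summary_fields <- function(s) {
    list(min = s$min, p25 = s$p25, median = s$median, p75 = s$p75, max = s$max,
         cf = s$class_fractions, bins = s$bins,
         n = c(s$n_included, s$n_excluded))
}
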