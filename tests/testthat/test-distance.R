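test_that("distance transform matches all-pairs brute force exactly", {
    for (i in seq_along(dyadic_spacings)) {
        sp <- dyadic_spacings[[i]]
        set.seed(100 + i)
        zs <- array(stats::runif(12^3) < 0.02, c(12, 12, 12))
        zs[6, 6, 6] <- TRUE
        d <- distance_transform(zs, spacing = sp)
        idx_all <- as.matrix(expand.grid(i = 1:12, j = 1:12, k = 1:12))
        zidx <- which(zs, arr.ind = TRUE, useNames = FALSE)
        o <- array(oracle_min_dist(idx_all, zidx, sp), c(12, 12, 12))
        expect_identical(d, o)
    }
    expect_error(distance_transform(array(FALSE, c(4, 4, 4))),
                 class = "qam_empty_structure_error")
})

test_that("signed map is zero on the ablation surface, signed by side", {
    abl <- rasterize_sphere(c(10, 10, 10), 12, c(21, 21, 21), role = "ablation")
    sdm <- signed_distance_map(abl)
    surf <- extract_surface(abl)
    expect_true(all(sdm$values[surf$indices] == 0))
    fg <- abl$voxels == 1L
    expect_true(all(sdm$values[fg] >= 0))
    expect_true(all(sdm$values[!fg] <= 0))
    # strictly negative off the surface outside
    expect_lt(max(sdm$values[!fg]), 0)
})

test_that("straight-line distances honor voxel spacing", {
    # slab ablation: outside voxel 3 steps beyond the surface on a 1 mm grid
    abl <- cuboid_mask(c(15, 15, 15), c(2, 2, 2), c(8, 14, 14),
                       role = "ablation")
    sdm <- signed_distance_map(abl)
    expect_identical(sdm$values[11, 8, 8], -3)

    # anisotropic: one step along the 2.5 mm axis
    abl2 <- cuboid_mask(c(15, 15, 9), c(2, 2, 2), c(14, 14, 5),
                        spacing = c(1, 1, 2.5), role = "ablation")
    sdm2 <- signed_distance_map(abl2)
    expect_identical(sdm2$values[8, 8, 6], -2.5)
})

test_that("background interior convention measures depth to non-ablated tissue", {
    abl <- rasterize_sphere(c(8, 8, 8), 10, c(17, 17, 17), role = "ablation")
    sdm <- signed_distance_map(abl, interior = "background")
    fg <- abl$voxels == 1L
    # surface voxels sit one voxel from background, not at zero
    surf <- extract_surface(abl)
    expect_true(all(sdm$values[surf$indices] >= 1))
    expect_true(all(sdm$values[fg] > 0))
    expect_true(all(sdm$values[!fg] < 0))
    # against brute force on the same grid
    idx_all <- as.matrix(expand.grid(i = 1:17, j = 1:17, k = 1:17))
    fg_idx <- which(fg, arr.ind = TRUE, useNames = FALSE)
    bg_idx <- which(!fg, arr.ind = TRUE, useNames = FALSE)
    o <- ifelse(fg, array(oracle_min_dist(idx_all, bg_idx, c(1, 1, 1)), dim(fg)),
                -array(oracle_min_dist(idx_all, fg_idx, c(1, 1, 1)), dim(fg)))
    expect_identical(sdm$values, o)
})
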