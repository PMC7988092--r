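test_that("sphere rasterization counts lattice points in the closed ball", {
    m <- rasterize_sphere(c(16, 16, 16), 10, c(33, 33, 33))
    expect_lt(abs(sum(m$voxels) - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.1)

    # vanishing diameter at a voxel center: exactly that voxel
    tiny <- rasterize_sphere(c(8, 8, 8), 1e-6, c(17, 17, 17))
    expect_identical(sum(tiny$voxels), 1L)
    expect_identical(tiny$voxels[9, 9, 9], 1L)

    # centered on a voxel center: symmetric under axis flips
    v <- rasterize_sphere(c(10, 10, 10), 9, c(21, 21, 21))$voxels
    expect_identical(v, v[21:1, , ])
    expect_identical(v, v[, , 21:1])

    expect_error(rasterize_sphere(c(3, 16, 16), 10, c(33, 33, 33)),
                 class = "qam_bounds_error")
})

test_that("random blob cases are reproducible, distinct across seeds, overlapping", {
    a <- random_blob_case(42L, 24L)
    b <- random_blob_case(42L, 24L)
    expect_identical(a$tumor$voxels, b$tumor$voxels)
    expect_identical(a$ablation$voxels, b$ablation$voxels)
    c2 <- random_blob_case(43L, 24L)
    expect_false(identical(a$tumor$voxels, c2$tumor$voxels) &&
                 identical(a$ablation$voxels, c2$ablation$voxels))
    expect_gt(sum(a$tumor$voxels & a$ablation$voxels), 0L)
})

test_that("the shifted-ablation phantom leaves uncovered tumor surface", {
    case <- phantom_case_T16()
    expect_null(case$liver)
    expect_identical(case$tumor$shape, case$ablation$shape)
    expect_equal(case$tumor$spacing, case$ablation$spacing)
    fit <- qam(case)
    expect_lt(min(fit$margins), 0)
})

test_that("the subcapsular phantom is fully covered and straddles the shell", {
    case <- phantom_case_T22()
    expect_false(is.null(case$liver))
    # full coverage: every tumor voxel inside the ablation
    expect_true(all(case$ablation$voxels[case$tumor$voxels == 1L] == 1L))
    fit_no <- qam(case, interior = "background")
    expect_true(all(fit_no$margins >= 0))
    fit_ex <- qam(case, subcapsular = TRUE, interior = "background")
    expect_gt(nrow(fit_ex$excluded), 0L)
    expect_gt(length(fit_ex$margins), 0L)
    # removing the capsule-adjacent voxels re-weights toward sufficient margins
    g_no <- summary(fit_no)$class_fractions["green"]
    g_ex <- summary(fit_ex)$class_fractions["green"]
    expect_gt(g_ex, g_no)
})

test_that("concentric phantoms track the closed-form radial margin", {
    for (dd in list(c(10, 16), c(8, 20))) {
        case <- phantom_case(tumor_center = c(24, 24, 24), tumor_diameter = dd[1],
                             ablation_center = c(24, 24, 24),
                             ablation_diameter = dd[2],
                             grid_shape = c(48L, 48L, 48L))
        fit <- qam(case)
        expect_true(all(abs(fit$margins - (dd[2] - dd[1]) / 2) <= sqrt(3)))
    }
})
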