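make_subcapsular <- function(capsule_z = 45, tumor_z = 40, grid = c(64L, 64L, 64L)) {
    tum <- rasterize_sphere(c(32, 32, tumor_z), 10, grid)
    liv <- rasterize_half_space_for_test(3L, capsule_z, grid)
    list(tumor_surface = extract_surface(tum), liver = liv, tumor = tum)
}

# planar liver built directly (the packaged half-space phantom is exercised
# through phantom_case; this keeps the fixture explicit)
rasterize_half_space_for_test <- function(axis, offset, grid) {
    v <- array(0L, grid)
    keep <- ((seq_len(grid[axis]) - 1)) <= offset
    if (axis == 3L) v[, , keep] <- 1L
    qam_mask(v, role = "liver")
}

test_that("threshold zero excludes nothing; exclusion grows with threshold", {
    sc <- make_subcapsular()
    ex0 <- exclude_subcapsular(sc$tumor_surface, sc$liver, threshold = 0)
    expect_identical(nrow(ex0$excluded), 0L)
    prev <- -1L
    for (thr in c(1, 2.5, 5, 7)) {
        ex <- exclude_subcapsular(sc$tumor_surface, sc$liver, threshold = thr)
        expect_gte(nrow(ex$excluded), prev)
        expect_identical(nrow(ex$excluded) + nrow(ex$included$indices),
                         nrow(sc$tumor_surface$indices))
        prev <- nrow(ex$excluded)
    }
})

test_that("a tumor far from the capsule keeps its whole surface", {
    # 10 mm tumor centered 13 mm below a planar capsule: min distance > 5 mm
    sc <- make_subcapsular(capsule_z = 45, tumor_z = 32)
    ex <- exclude_subcapsular(sc$tumor_surface, sc$liver, threshold = 5)
    expect_identical(nrow(ex$excluded), 0L)
})

test_that("tangent tumor: excluded set equals the brute-force rule", {
    sc <- make_subcapsular(capsule_z = 45, tumor_z = 40)  # tangent at z=45
    ts <- sc$tumor_surface
    ex <- exclude_subcapsular(ts, sc$liver, threshold = 5)
    expect_gt(nrow(ex$excluded), 0L)
    expect_gt(nrow(ex$included$indices), 0L)
    lsurf <- oracle_surface(sc$liver$voxels)
    d <- oracle_min_dist(ts$indices, lsurf, c(1, 1, 1))
    expect_identical(sort_rows(ex$excluded),
                     sort_rows(ts$indices[d < 5, , drop = FALSE]))
})

test_that("tumors entirely within the exclusion shell raise the documented error", {
    grid <- c(32L, 32L, 32L)
    tum <- rasterize_sphere(c(16, 16, 26), 4, grid)   # < 5 mm wide, at capsule
    liv <- rasterize_half_space_for_test(3L, 28, grid)
    expect_error(exclude_subcapsular(extract_surface(tum), liv, threshold = 5),
                 regexp = "no surface distances",
                 class = "qam_all_excluded_error")
})

test_that("tumor surface outside the liver foreground warns", {
    grid <- c(32L, 32L, 32L)
    tum <- rasterize_sphere(c(16, 16, 20), 10, grid)   # pokes through capsule
    liv <- rasterize_half_space_for_test(3L, 22, grid)
    expect_warning(exclude_subcapsular(extract_surface(tum), liv, threshold = 1),
                   class = "qam_subcapsular_warning")
})
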