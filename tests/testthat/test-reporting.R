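fake_fit <- function(margins) {
    structure(list(margins = margins,
                   included = list(indices = cbind(seq_along(margins),
                                                   seq_along(margins),
                                                   seq_along(margins))),
                   excluded = matrix(integer(0), 0L, 3L),
                   case_id = "synthetic"),
              class = "qam")
}

test_that("traffic-light classification uses half-open class intervals", {
    cl <- classify_margin(c(-0.5, -1e-9, 0, 2.5, 4.999999, 5, 8))
    expect_identical(as.character(cl),
                     c("orange", "orange", "yellow", "yellow", "yellow",
                       "green", "green"))
    # configurable bounds
    expect_identical(as.character(classify_margin(c(0, 9.9, 10), low = 1, high = 10)),
                     c("orange", "yellow", "green"))
    expect_error(classify_margin(1, low = 5, high = 5), class = "qam_io_error")
})

test_that("summary reports percentiles, class fractions and substrata bins", {
    s <- summary(fake_fit(c(-2, -1, 0, 1, 2)))
    expect_identical(c(s$min, s$p25, s$median, s$p75, s$max), c(-2, -1, 0, 1, 2))
    expect_equal(unname(s$class_fractions), c(40, 60, 0))
    expect_equal(sum(s$bins$percent), 100)

    z <- summary(fake_fit(rep(0, 17)))
    expect_identical(c(z$min, z$median, z$max), c(0, 0, 0))
    expect_equal(unname(z$class_fractions), c(0, 100, 0))
    expect_identical(z$bins$center, 0)
    expect_equal(z$bins$percent, 100)

    expect_error(summary(fake_fit(numeric(0))), class = "qam_all_excluded_error")
})

test_that("summary is permutation-invariant and fractions always total 100", {
    set.seed(7)
    for (rep in 1:5) {
        m <- stats::rnorm(200, mean = 2, sd = 3)
        a <- summary(fake_fit(m))
        b <- summary(fake_fit(sample(m)))
        expect_identical(summary_fields(a), summary_fields(b))
        expect_lt(abs(sum(a$class_fractions) - 100), 1e-9)
        expect_lt(abs(sum(a$bins$percent) - 100), 1e-9)
    }
})

test_that("class fractions come from raw margins and agree with interior bins", {
    # margins placed away from the straddling bins at 0 and 5 mm: class
    # fractions must then equal the bin sums inside each class
    m <- c(-3.2, -1.4, 1.1, 2.2, 3.3, 3.6, 6.1, 7.4)
    s <- summary(fake_fit(m))
    agg <- tapply(s$bins$percent, s$bins$class, sum, default = 0)
    expect_equal(unname(s$class_fractions), as.numeric(agg))
    # a margin of 4.7 falls in the straddling bin centered at 5 but is yellow
    s2 <- summary(fake_fit(c(4.7, 6)))
    expect_equal(unname(s2$class_fractions), c(0, 50, 50))
    expect_identical(s2$bins$center, c(5, 6))
})

test_that("nearest-rank percentiles are available as an option", {
    s <- summary(fake_fit(c(1, 2, 3, 10)), percentile_method = "nearest")
    expect_identical(s$p25, 1)
    expect_identical(s$median, 2)
})

test_that("summary JSON and per-voxel CSV round-trip", {
    fit <- qam(phantom_case_T16(), interior = "background")
    s <- summary(fit)
    p <- tempfile(fileext = ".json")
    write_qam_summary(s, p)
    rec <- jsonlite::read_json(p, simplifyVector = TRUE)
    expect_equal(rec$distances_mm$min, s$min)
    expect_equal(rec$class_fractions_percent$orange,
                 unname(s$class_fractions["orange"]))
    expect_equal(rec$n_included, s$n_included)

    expect_error(write_qam_summary(s, file.path(tempfile(), "x", "y.json")),
                 class = "qam_io_error")

    csv <- tempfile(fileext = ".csv")
    write_qam_distances(fit, csv)
    df <- utils::read.csv(csv)
    expect_identical(names(df), c("i", "j", "k", "margin_mm", "excluded"))
    expect_identical(nrow(df), length(fit$margins))

    # excluded voxels appear as flagged rows without a margin value
    fit22 <- qam(phantom_case_T22(), subcapsular = TRUE, interior = "background")
    csv2 <- tempfile(fileext = ".csv")
    write_qam_distances(fit22, csv2)
    df2 <- utils::read.csv(csv2)
    expect_identical(sum(df2$excluded), nrow(fit22$excluded))
    expect_true(all(is.na(df2$margin_mm[df2$excluded])))
    expect_true(all(!is.na(df2$margin_mm[!df2$excluded])))
})
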