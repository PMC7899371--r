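test_that("panels round-trip through CSV unchanged", {
  for (panel in list(toy_panel(), random_panel(100))) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_panel(panel, path)
    back <- read_panel(path)
    expect_equal(
      dplyr::arrange(back, measure, metric, location_id, year, sex, age_group),
      dplyr::arrange(panel[, names(back)], measure, metric, location_id, year,
                     sex, age_group)
    )
  }
  # empty panel -> header-only file, still readable
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(toy_panel()[0, ], path)
  expect_length(readLines(path), 1L)
  expect_equal(nrow(read_panel(path)), 0L)
})

test_that("read_panel normalizes GBD vocabulary and column order", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "lower,val,upper,measure,location,sex,age,year,metric",
    "2,3,4,Deaths,Global,Both,age_standardized,2017,Rate",
    "1,2,3,DALYs (Disability-Adjusted Life Years),Global,Female,all_ages,2017,Number"
  ), path)
  panel <- read_panel(path)
  expect_setequal(panel$measure, c("deaths", "daly"))
  expect_setequal(panel$metric, c("rate_per_100k", "count"))
  expect_setequal(panel$sex, c("both", "female"))
})

test_that("invalid panels are rejected with offending rows reported", {
  bad <- toy_panel()
  bad$lower[2] <- 5; bad$value[2] <- 3  # lower > value
  err <- expect_error(validate_panel(bad), class = "qcindex_validation_error")
  expect_match(paste(conditionMessage(err), collapse = " "), "rows 2")

  dup <- dplyr::bind_rows(toy_panel(), toy_panel()[1, ])
  expect_error(validate_panel(dup), class = "qcindex_validation_error")

  neg <- toy_panel(); neg$value[1] <- -1; neg$lower[1] <- -2
  expect_error(validate_panel(neg), class = "qcindex_validation_error")

  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("measure,location,sex,age,year,val,upper,lower", path)  # no metric
  expect_error(read_panel(path), class = "qcindex_format_error")
  expect_error(read_panel(path), "metric")
})

test_that("crude_rate scales counts per 100,000 and rejects bad denominators", {
  expect_equal(crude_rate(0, 1e6), 0)
  expect_equal(crude_rate(100, 1e5), 100)
  # back-solved 1990 global incidence: 194,000 cases at rate 3.97 per 100k
  expect_equal(crude_rate(194000, 4.887e9), 3.97, tolerance = 0.001)
  expect_error(crude_rate(1, 0), class = "qcindex_domain_error")
  expect_error(crude_rate(-1, 10), class = "qcindex_domain_error")
})

test_that("age_standardize matches hand-computed weighted sums", {
  w <- standard_population(c("0-4" = 0.2, "5-9" = 0.3, "10-14" = 0.5))
  counts <- c("0-4" = 5, "5-9" = 20, "10-14" = 90)
  pops <- c("0-4" = 1000, "5-9" = 2000, "10-14" = 3000)
  # band rates 500, 1000, 3000 -> 0.2*500 + 0.3*1000 + 0.5*3000 = 1900
  expect_equal(age_standardize(counts, pops, w), 1900)
  # single band with weight 1 equals the crude rate
  expect_equal(
    age_standardize(c("0-4" = 7), c("0-4" = 1400), c("0-4" = 1)),
    crude_rate(7, 1400)
  )
  expect_error(
    age_standardize(counts, pops["0-4"], w),
    class = "qcindex_alignment_error"
  )
})

test_that("uniform age-specific rates are invariant to the standard population", {
  set.seed(11)
  bands <- age_bands()
  for (i in 1:20) {
    w <- runif(length(bands)); w <- setNames(w / sum(w), bands)
    pops <- setNames(runif(length(bands), 1e3, 1e6), bands)
    r <- runif(1, 1, 50)
    counts <- r / 1e5 * pops
    expect_equal(age_standardize(counts, pops, standard_population(w)), r,
                 tolerance = 1e-9)
  }
})

test_that("standard population weights must be a proper distribution", {
  expect_error(standard_population(c("0-4" = 0.4, "5-9" = 0.4)),
               class = "qcindex_domain_error")
  expect_error(standard_population(c(0.5, 0.5)), class = "qcindex_domain_error")
  w <- world_standard_population()
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_setequal(names(w), age_bands())
})

test_that("interval non-overlap significance is symmetric with closed endpoints", {
  expect_true(ui_overlap_significant(c(10.28, 14.76), c(18.96, 24.47)))
  expect_false(ui_overlap_significant(c(3.32, 4.71), c(4.46, 5.63)))
  expect_false(ui_overlap_significant(c(0, 1), c(1, 2)))  # endpoint touch
  set.seed(3)
  for (i in 1:25) {
    a <- sort(runif(2, 0, 10)); b <- sort(runif(2, 0, 10))
    expect_identical(ui_overlap_significant(a, b), ui_overlap_significant(b, a))
  }
  expect_error(ui_overlap_significant(c(2, 1), c(0, 1)),
               class = "qcindex_domain_error")
})
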