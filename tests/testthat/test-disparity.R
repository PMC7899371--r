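test_that("GDR is the female-to-male quotient with reciprocal symmetry", {
  expect_equal(compute_gdr(54, 54), 1)
  expect_equal(compute_gdr(54, 50), 1.08)
  expect_error(compute_gdr(10, 0), class = "qcindex_undefined_gdr_error")
  set.seed(4)
  a <- runif(20, 1, 100); b <- runif(20, 1, 100)
  expect_equal(compute_gdr(a, b) * compute_gdr(b, a), rep(1, 20),
               tolerance = 1e-12)
  expect_true(all((compute_gdr(a, b) == 1) == (a == b)))
})

test_that("five-year bands partition into childhood, adulthood, elderly", {
  expect_equal(assign_age_group("15-19"), "childhood")
  expect_equal(assign_age_group("60-64"), "adulthood")
  expect_equal(assign_age_group("70-74"), "elderly")
  groups <- assign_age_group(age_bands())
  expect_true(all(groups %in% c("childhood", "adulthood", "elderly")))
  expect_equal(sum(groups == "childhood"), 4)   # 0-4 ... 15-19
  expect_equal(sum(groups == "adulthood"), 9)   # 20-24 ... 60-64
  expect_equal(sum(groups == "elderly"), 7)     # 65-69 ... 95+
  # alternative scheme (18-year childhood cut) is configurable
  alt <- age_group_scheme(childhood_max = 15, elderly_min = 65)
  expect_equal(assign_age_group("15-19", alt), "adulthood")
  expect_error(assign_age_group("teenagers"), class = "qcindex_domain_error")
})

test_that("age-group pooling is ratio-of-sums and respects degenerate pools", {
  sim <- small_sim()
  by_group <- qci_by_age_group(sim$panel, sim$model, sexes = "both",
                               years = 2000)
  expect_setequal(unique(by_group$age_group),
                  c("childhood", "adulthood", "elderly"))
  # pooling by hand for one country/group reproduces the ratio quartet
  counts <- dplyr::filter(sim$panel, metric == "count", sex == "both",
                          year == 2000, location_id == "C001",
                          age_group %in% age_bands()[1:4])
  pooled <- tapply(counts$value, counts$measure, sum)
  row <- dplyr::filter(by_group, location_id == "C001",
                       age_group == "childhood")
  z <- (pooled[["deaths"]] / pooled[["incidence"]] -
          sim$model$mu[["mir"]]) / sim$model$sigma[["mir"]]
  expect_equal(row$zeta_mir, unname(z), tolerance = 1e-12)
  # pooling two identical bands leaves the ratios unchanged
  one_band <- dplyr::filter(sim$panel, metric == "count", age_group == "40-44")
  doubled <- dplyr::bind_rows(one_band,
                              dplyr::mutate(one_band, age_group = "45-49"))
  q1 <- qci_by_age_group(one_band, sim$model, sexes = "both", years = 2000)
  q2 <- qci_by_age_group(doubled, sim$model, sexes = "both", years = 2000)
  expect_equal(q2$qci, q1$qci, tolerance = 1e-12)
})

test_that("age-group QCI ranking follows the generator's quality gradient", {
  sim <- small_sim()
  by_group <- qci_by_age_group(sim$panel, sim$model, sexes = "both")
  world_q <- sim$world$countries$latent_quality
  means <- by_group |>
    dplyr::group_by(location_id) |>
    dplyr::summarise(qci = mean(qci))
  expect_gt(cor(means$qci,
                world_q[match(means$location_id, sim$world$countries$location_id)],
                method = "spearman"), 0.9)
})

test_that("SDI quintiles are deterministic equal-count bins", {
  five <- tibble::tibble(location_id = letters[1:5], sdi = c(.9, .1, .5, .3, .7))
  q5 <- assign_sdi_quintiles(five)
  expect_equal(as.character(q5$sdi_quintile[order(q5$sdi)]),
               c("low", "low-middle", "middle", "high-middle", "high"))
  set.seed(10)
  hundred <- tibble::tibble(location_id = sprintf("L%03d", 1:100),
                            sdi = runif(100))
  expect_true(all(table(assign_sdi_quintiles(hundred)$sdi_quintile) == 20))
  tied <- tibble::tibble(location_id = sprintf("L%02d", 10:1),
                         sdi = rep(0.5, 10))
  expect_identical(assign_sdi_quintiles(tied), assign_sdi_quintiles(tied))
  expect_error(assign_sdi_quintiles(five[1:4, ]), class = "qcindex_domain_error")
})

test_that("leave-one-out outlier flags match the three-sigma rule", {
  expect_false(any(flag_outliers(rep(1, 10))))
  # a lone country far above a tight cluster (the published outlier pattern)
  set.seed(6)
  gdr <- c(rnorm(49, 1, 0.01), 1.78)
  flags <- flag_outliers(gdr)
  expect_true(flags[50])
  expect_false(any(flags[1:49]))
  # a symmetric pair far from a tight cluster flags both
  v <- c(rep(1, 20), 5, -3)
  flags2 <- flag_outliers(v)
  expect_true(all(flags2[21:22]))
  expect_false(any(flags2[1:20]))
  expect_error(flag_outliers(c(1, 2)), class = "qcindex_domain_error")
})

test_that("gender disparity follows the SDI gradient built into the generator", {
  sim <- small_sim()
  gdr <- compute_gdr_table(sim$panel, sim$model)
  # female QCI can clip to 0 at the very worst stratum, so GDR >= 0
  expect_true(all(is.finite(gdr$gdr) & gdr$gdr >= 0))
  expect_true(all(c("qci_female", "qci_male", "gdr", "outlier") %in% names(gdr)))
  quintiles <- assign_sdi_quintiles(
    dplyr::select(sim$world$countries, location_id, sdi))
  means <- gdr |>
    dplyr::left_join(dplyr::select(quintiles, location_id, sdi_quintile),
                     by = "location_id") |>
    dplyr::group_by(sdi_quintile) |>
    dplyr::summarise(gdr = mean(gdr))
  expect_lt(means$gdr[means$sdi_quintile == "low"], 1)
  expect_lt(abs(means$gdr[means$sdi_quintile == "high"] - 1), 0.1)
  # flags never remove rows: aggregates identical with and without the column
  expect_equal(mean(gdr$gdr), mean(dplyr::select(gdr, -outlier)$gdr))
})
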