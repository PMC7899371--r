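test_that("secondary ratios match hand division of published global rates", {
  ratios <- compute_secondary_ratios(toy_panel())
  expect_equal(nrow(ratios), 1L)
  expect_equal(ratios$mir, 3.11 / 5.16, tolerance = 1e-12)        # ~0.6028
  expect_equal(ratios$yll_to_yld, 109.78 / 2.13, tolerance = 1e-12) # ~51.54
  expect_equal(ratios$daly_to_prev, 111.91 / 22.01, tolerance = 1e-12)
  expect_equal(ratios$prev_to_inc, 22.01 / 5.16, tolerance = 1e-12)
})

test_that("zero numerators are fine, zero denominators excluded with a warning", {
  p <- toy_panel()
  p$value[p$measure == "deaths"] <- 0
  p$lower[p$measure == "deaths"] <- 0
  expect_equal(compute_secondary_ratios(p)$mir, 0)

  p2 <- dplyr::bind_rows(
    toy_panel(),
    dplyr::mutate(toy_panel(), location_id = "ZWE", location_name = "ZWE")
  )
  p2$value[p2$location_id == "ZWE" & p2$measure == "incidence"] <- 0
  p2$lower[p2$location_id == "ZWE" & p2$measure == "incidence"] <- 0
  expect_warning(r <- compute_secondary_ratios(p2), "excluded")
  expect_equal(r$location_id, "AFG")
  expect_equal(attr(r, "excluded")$location_id, "ZWE")

  p3 <- toy_panel()[toy_panel()$measure != "yll", ]
  expect_error(compute_secondary_ratios(p3), class = "qcindex_data_error")
  expect_error(compute_secondary_ratios(p3), "yll")
})

test_that("standardization is the componentwise z-score", {
  mu <- setNames(c(0.5, 40, 5, 4), ratio_names())
  sigma <- setNames(c(0.1, 10, 2, 1), ratio_names())
  q <- tibble::tibble(mir = 0.5, yll_to_yld = 50, daly_to_prev = 1, prev_to_inc = 2)
  z <- standardize_ratios(q, mu, sigma)
  expect_equal(unlist(z[1, ratio_names()]),
               setNames(c(0, 1, -2, -2), ratio_names()))
  expect_error(standardize_ratios(q, mu, replace(sigma, 2, 0)),
               class = "qcindex_degenerate_error")
})

test_that("published fixed-coefficient score is an exact linear form", {
  expect_identical(fixed_coefficient_score(c(1, 0, 0, 0)), 0.5003587)
  expect_identical(fixed_coefficient_score(c(0, 1, 0, 0)), 0.5007964)
  expect_identical(fixed_coefficient_score(c(0, 0, 1, 0)), 0.5002090)
  expect_identical(fixed_coefficient_score(c(0, 0, 0, 1)), -0.4986332)
  expect_identical(fixed_coefficient_score(c(0, 0, 0, 0)), 0)
  # linearity: score(a) + score(b) = score(a + b)
  set.seed(8)
  for (i in 1:10) {
    a <- rnorm(4); b <- rnorm(4)
    expect_equal(fixed_coefficient_score(a) + fixed_coefficient_score(b),
                 fixed_coefficient_score(a + b), tolerance = 1e-12)
  }
  # hand dot product on a random vector
  z <- c(0.3, -1.2, 2.0, 0.7)
  expect_equal(fixed_coefficient_score(z),
               0.5003587 * 0.3 + 0.5007964 * -1.2 + 0.5002090 * 2.0 +
                 -0.4986332 * 0.7,
               tolerance = 1e-15)
})

test_that("fitted loadings agree with an independent PCA up to sign", {
  set.seed(21)
  for (i in 1:10) {
    x <- matrix(rnorm(200 * 4), ncol = 4) %*% matrix(rnorm(16), 4)
    q <- setNames(as.data.frame(x), ratio_names())
    q <- dplyr::mutate(q, location_id = as.character(dplyr::row_number()),
                       year = 2000L, sex = "both", age_group = "age_standardized")
    model <- fit_qci_model(tibble::as_tibble(q))
    oracle <- unname(stats::prcomp(x, scale. = TRUE)$rotation[, 1])
    fitted <- unname(model$loadings)
    expect_equal(sqrt(sum(fitted^2)), 1, tolerance = 1e-9)
    flip <- sign(sum(fitted * oracle))
    expect_equal(fitted, flip * oracle, tolerance = 1e-8)
  }
})

test_that("perfectly correlated ratios give the equal-loading limit", {
  base <- seq(1, 3, length.out = 50)
  q <- tibble::tibble(
    location_id = as.character(1:50), year = 2000L, sex = "both",
    age_group = "age_standardized",
    mir = base, yll_to_yld = 2 * base + 1, daly_to_prev = 0.5 * base,
    prev_to_inc = -base + 10
  )
  model <- fit_qci_model(q)
  expect_equal(abs(unname(model$loadings)), rep(0.5, 4), tolerance = 1e-9)
})

test_that("the first component beats random unit directions in variance share", {
  sim <- small_sim()
  z <- scale(as.matrix(sim$ratios[, ratio_names()]))
  pc_var <- stats::var(drop(z %*% sim$model$loadings))
  set.seed(13)
  for (i in 1:1000) {
    u <- rnorm(4); u <- u / sqrt(sum(u^2))
    expect_lte(stats::var(drop(z %*% u)), pc_var + 1e-12)
  }
})

test_that("orientation makes higher QCI mean better care, whatever the eigensign", {
  sim <- small_sim()
  model <- sim$model
  scored <- sim$qci
  expect_lt(cor(scored$qci, sim$ratios$mir), 0)
  flipped <- fit_qci_model(sim$ratios, loadings = -model$loadings)
  expect_equal(score_quartets(sim$ratios, flipped)$qci, scored$qci,
               tolerance = 1e-9)
})

test_that("scores are zero at the reference mean and rescale to 0/50/100", {
  sim <- small_sim()
  model <- sim$model
  at_mu <- tibble::tibble(location_id = "x", year = 2000L, sex = "both",
                          age_group = "age_standardized",
                          mir = model$mu[["mir"]],
                          yll_to_yld = model$mu[["yll_to_yld"]],
                          daly_to_prev = model$mu[["daly_to_prev"]],
                          prev_to_inc = model$mu[["prev_to_inc"]])
  expect_equal(pca_score(model, at_mu), 0, tolerance = 1e-12)
  expect_equal(rescale_to_qci(model, model$score_max), 100)
  expect_equal(rescale_to_qci(model, model$score_min), 0)
  expect_equal(rescale_to_qci(model, (model$score_min + model$score_max) / 2), 50)
  # clipping outside the reference range
  expect_equal(rescale_to_qci(model, model$score_max + 1), 100)
  expect_equal(rescale_to_qci(model, model$score_min - 1), 0)
  # reference extremes are attained in the scored table
  expect_equal(max(sim$qci$qci), 100)
  expect_equal(min(sim$qci$qci), 0)
})

test_that("QCI is invariant to a common affine rescaling of one ratio", {
  sim <- small_sim()
  for (r in c("mir", "prev_to_inc")) {
    shifted <- dplyr::mutate(sim$ratios, !!r := 3.7 * .data[[r]] + 11)
    model2 <- fit_qci_model(shifted)
    expect_equal(score_quartets(shifted, model2)$qci, sim$qci$qci,
                 tolerance = 1e-8)
  }
})

test_that("QCI moves in the care-quality direction of each ratio", {
  sim <- small_sim()
  model <- sim$model
  oriented <- model$orientation * model$loadings
  expect_lt(oriented[["mir"]], 0)
  expect_lt(oriented[["yll_to_yld"]], 0)
  expect_lt(oriented[["daly_to_prev"]], 0)
  expect_gt(oriented[["prev_to_inc"]], 0)
  base <- sim$ratios[3, ]
  bump <- function(col, d) {
    q <- base; q[[col]] <- q[[col]] + d
    pca_score(model, q)
  }
  s0 <- pca_score(model, base)
  expect_lt(bump("mir", 0.05), s0)
  expect_lt(bump("yll_to_yld", 1), s0)
  expect_lt(bump("daly_to_prev", 0.5), s0)
  expect_gt(bump("prev_to_inc", 0.5), s0)
})

test_that("degenerate reference sets are refused", {
  q <- toy_panel()
  expect_error(fit_qci_model(compute_secondary_ratios(q)),
               class = "qcindex_domain_error")  # < 5 strata
  const <- tibble::tibble(
    location_id = as.character(1:10), year = 2000L, sex = "both",
    age_group = "age_standardized",
    mir = 0.5, yll_to_yld = 1:10, daly_to_prev = 10:1, prev_to_inc = (1:10)^2
  )
  expect_error(fit_qci_model(const), class = "qcindex_degenerate_error")
})

test_that("models serialize to YAML and back exactly enough for re-use", {
  sim <- small_sim()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_qci_model(sim$model, path)
  back <- read_qci_model(path)
  expect_equal(back$mu, sim$model$mu, tolerance = 1e-14)
  expect_equal(back$loadings, sim$model$loadings, tolerance = 1e-14)
  expect_identical(back$orientation, sim$model$orientation)
  expect_equal(score_quartets(sim$ratios, back)$qci, sim$qci$qci,
               tolerance = 1e-10)
})

test_that("tidy and glance summarize the model", {
  sim <- small_sim()
  td <- generics::tidy(sim$model)
  expect_equal(td$ratio, ratio_names())
  expect_equal(sqrt(sum(td$loading^2)), 1, tolerance = 1e-9)
  gl <- generics::glance(sim$model)
  expect_equal(gl$n_reference, nrow(sim$ratios))
  expect_lt(gl$score_min, gl$score_max)
})
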