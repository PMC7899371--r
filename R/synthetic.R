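# Seeded generator of GBD-like burden panels with known latent care quality.
# The latent structure is the ground truth that the QCI pipeline must recover
# in the end-to-end tests.

default_incidence_age_profile <- function() {
  setNames(
    c(0.9, 0.6, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0, 1.2, 1.5,
      1.9, 2.3, 2.8, 3.3, 3.8, 4.2, 4.4, 4.3, 4.0, 3.6),
    age_bands()
  )
}

default_residual_life_expectancy <- function() {
  setNames(
    c(87.5, 83.0, 78.1, 73.2, 68.3, 63.4, 58.5, 53.6, 48.8, 44.0,
      39.3, 34.7, 30.2, 25.8, 21.6, 17.6, 13.9, 10.5, 7.6, 5.3),
    age_bands()
  )
}

#' Configuration of the synthetic GBD-like world
#'
#' Full parameterization (including the seed) of the synthetic generator.
#' Defaults describe a 100-country, 1990-2017 world in which a latent care
#' quality `q` rises with a synthetic socio-demographic index (SDI), the
#' mortality-to-incidence ratio falls with `q` through a logistic link,
#' disease survival rises with `q`, and a log-scale gender gap makes care
#' male-favoring at low SDI and near gender parity at high SDI.
#'
#' @param n_countries Number of countries (>= 2).
#' @param years Inclusive integer year range.
#' @param age_bands_used Fine 5-year age bands covering 0 to 95+.
#' @param seed Integer seed; every generator output is a deterministic
#'   function of the configuration including this seed.
#' @param sdi_range Interval in (0, 1) from which country SDI is drawn
#'   uniformly.
#' @param quality_sdi_slope Strength of the SDI -> quality link.
#' @param quality_noise_sd SD of country-level quality noise around the SDI
#'   line.
#' @param gender_gap_base,gender_gap_sdi_slope Log-scale female-vs-male
#'   quality offset `delta = base + slope * sdi`; sex-specific quality is
#'   `q * exp(+delta/2)` (female) and `q * exp(-delta/2)` (male). Negative
#'   `delta` means worse care for females.
#' @param baseline_incidence_per_100k All-ages reference incidence rate
#'   before age-profile scaling.
#' @param incidence_age_profile Named multiplier per age band.
#' @param mir_logistic_params `c(intercept, slope)`: MIR = plogis(intercept
#'   + slope * q), strictly inside (0, 1); slope < 0 so better care lowers
#'   case fatality.
#' @param survival_years_params `c(intercept, slope)`: mean years lived with
#'   the disease = intercept + slope * q (kept >= 0.5).
#' @param disability_weight YLD per prevalent case-year, in (0, 1).
#' @param residual_life_expectancy Named years of remaining life expectancy
#'   per age band (YLL per death).
#' @param noise_cv Coefficient of variation of the mean-one multiplicative
#'   lognormal noise applied per measure (DALY excepted: it is always the
#'   exact post-noise sum YLL + YLD).
#' @param ui_halfwidth_frac Half-width of the symmetric multiplicative 95%
#'   uncertainty band, as a fraction of the value.
#' @param population_lognormal `c(meanlog, sdlog)` of total country
#'   population.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_countries = 100,
                             years = 1990:2017,
                             age_bands_used = age_bands(),
                             seed = 20170L,
                             sdi_range = c(0.2, 0.95),
                             quality_sdi_slope = 1.0,
                             quality_noise_sd = 0.05,
                             gender_gap_base = -0.30,
                             gender_gap_sdi_slope = 0.33,
                             baseline_incidence_per_100k = 5,
                             incidence_age_profile = default_incidence_age_profile(),
                             mir_logistic_params = c(1.73, -3.47),
                             survival_years_params = c(1.0, 6.0),
                             disability_weight = 0.12,
                             residual_life_expectancy = default_residual_life_expectancy(),
                             noise_cv = 0.08,
                             ui_halfwidth_frac = 0.15,
                             population_lognormal = c(log(1e7), 0.7)) {
  config <- list(
    n_countries = as.integer(n_countries), years = as.integer(years),
    age_bands_used = age_bands_used, seed = as.integer(seed),
    sdi_range = sdi_range, quality_sdi_slope = quality_sdi_slope,
    quality_noise_sd = quality_noise_sd, gender_gap_base = gender_gap_base,
    gender_gap_sdi_slope = gender_gap_sdi_slope,
    baseline_incidence_per_100k = baseline_incidence_per_100k,
    incidence_age_profile = incidence_age_profile,
    mir_logistic_params = mir_logistic_params,
    survival_years_params = survival_years_params,
    disability_weight = disability_weight,
    residual_life_expectancy = residual_life_expectancy,
    noise_cv = noise_cv, ui_halfwidth_frac = ui_halfwidth_frac,
    population_lognormal = population_lognormal
  )
  if (config$n_countries < 2) {
    abort("`n_countries` must be at least 2.", class = "qcindex_config_error")
  }
  if (length(config$sdi_range) != 2 || config$sdi_range[1] <= 0 ||
      config$sdi_range[2] >= 1 || diff(config$sdi_range) <= 0) {
    abort("`sdi_range` must be an increasing interval inside (0, 1).",
          class = "qcindex_config_error")
  }
  if (config$quality_noise_sd < 0 || config$noise_cv < 0) {
    abort("Noise parameters must be non-negative.", class = "qcindex_config_error")
  }
  if (config$disability_weight <= 0 || config$disability_weight >= 1) {
    abort("`disability_weight` must lie in (0, 1).", class = "qcindex_config_error")
  }
  if (config$ui_halfwidth_frac <= 0 || config$ui_halfwidth_frac >= 1) {
    abort("`ui_halfwidth_frac` must lie in (0, 1).", class = "qcindex_config_error")
  }
  missing_profile <- setdiff(config$age_bands_used, names(config$incidence_age_profile))
  missing_rle <- setdiff(config$age_bands_used, names(config$residual_life_expectancy))
  if (length(missing_profile) > 0 || length(missing_rle) > 0) {
    abort("incidence_age_profile and residual_life_expectancy must cover every age band.",
          class = "qcindex_config_error")
  }
  structure(config, class = "synthetic_config")
}

mean_one_lognormal <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate the synthetic world: countries, latent quality, populations
#'
#' Draws country SDI uniformly on `sdi_range`, latent care quality
#' `q = quality_sdi_slope * sdi + N(0, quality_noise_sd)` (floored at 0.01 so
#' the multiplicative sex offset preserves ordering), sex-specific quality
#' through the log-scale gender gap, and a fixed-pyramid population split
#' evenly by sex. Deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return List of class `synthetic_world` with tibbles `countries`
#'   (`location_id, location_name, sdi, latent_quality, quality_female,
#'   quality_male`) and `population` (`location_id, sex, age_group,
#'   population`), plus the `config`.
#' @export
generate_world <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_countries
  ids <- sprintf("C%03d", seq_len(n))
  sdi <- runif(n, config$sdi_range[1], config$sdi_range[2])
  quality <- pmax(config$quality_sdi_slope * sdi +
                    rnorm(n, 0, config$quality_noise_sd), 0.01)
  delta <- config$gender_gap_base + config$gender_gap_sdi_slope * sdi
  countries <- tibble(
    location_id = ids, location_name = ids,
    sdi = sdi, latent_quality = quality,
    quality_female = quality * exp(delta / 2),
    quality_male = quality * exp(-delta / 2)
  )
  total_pop <- rlnorm(n, config$population_lognormal[1], config$population_lognormal[2])
  pyramid <- exp(-0.035 * age_band_start(config$age_bands_used))
  pyramid <- pyramid / sum(pyramid)
  population <- tidyr::expand_grid(
    location_id = ids, sex = c("female", "male"),
    age_group = config$age_bands_used
  ) %>%
    mutate(population = total_pop[match(.data$location_id, ids)] *
             pyramid[match(.data$age_group, config$age_bands_used)] / 2)
  structure(list(countries = countries, population = population, config = config),
            class = "synthetic_world")
}

#' Generate a GBD-like burden panel from a synthetic world
#'
#' For each (country, year, sex, age band): incidence counts follow the
#' baseline rate and age profile; deaths = MIR(q) x incidence; prevalence =
#' incidence x survival years(q); YLL = deaths x residual life expectancy;
#' YLD = prevalence x disability weight. Mean-one multiplicative lognormal
#' noise (cv = `noise_cv`) is applied per measure and year; DALY is then the
#' exact rowwise sum YLL + YLD at every aggregation level, so the accounting
#' identity holds bit-exactly. Emits counts and rates per 100,000 for fine
#' bands and `all_ages`, age-standardized rates (via [age_standardize()]
#' weights from [world_standard_population()]), and a `both`-sex stratum
#' pooled by population. Uncertainty intervals are `value * (1 -/+
#' ui_halfwidth_frac)`.
#'
#' @param world A [generate_world()] result.
#' @param config Configuration; defaults to the one stored in `world`.
#' @param std_pop Standard population for age-standardized rates.
#' @return A validated burden panel tibble (see [validate_panel()]).
#' @export
generate_epi_panel <- function(world, config = world$config,
                               std_pop = world_standard_population()) {
  stopifnot(inherits(world, "synthetic_world"))
  set.seed(config$seed + 1L)
  bands <- config$age_bands_used

  core <- tidyr::expand_grid(
    location_id = world$countries$location_id,
    year = config$years,
    sex = c("female", "male"),
    age_group = bands
  ) %>%
    left_join(world$population, by = c("location_id", "sex", "age_group")) %>%
    left_join(select(world$countries, "location_id", "quality_female", "quality_male"),
              by = "location_id") %>%
    mutate(
      q = ifelse(.data$sex == "female", .data$quality_female, .data$quality_male),
      mir = plogis(config$mir_logistic_params[1] + config$mir_logistic_params[2] * .data$q),
      surv = pmax(config$survival_years_params[1] +
                    config$survival_years_params[2] * .data$q, 0.5),
      incidence0 = config$baseline_incidence_per_100k / 1e5 *
        config$incidence_age_profile[.data$age_group] * .data$population,
      deaths0 = .data$mir * .data$incidence0,
      prevalence0 = .data$incidence0 * .data$surv,
      yll0 = .data$deaths0 * config$residual_life_expectancy[.data$age_group],
      yld0 = .data$prevalence0 * config$disability_weight
    )

  nr <- nrow(core)
  noisy <- core %>%
    mutate(
      incidence = .data$incidence0 * mean_one_lognormal(nr, config$noise_cv),
      prevalence = pmax(.data$prevalence0 * mean_one_lognormal(nr, config$noise_cv),
                        .data$incidence0 * 1e-6),
      deaths = .data$deaths0 * mean_one_lognormal(nr, config$noise_cv),
      yll = .data$yll0 * mean_one_lognormal(nr, config$noise_cv),
      yld = .data$yld0 * mean_one_lognormal(nr, config$noise_cv)
    ) %>%
    select("location_id", "year", "sex", "age_group", "population",
           "incidence", "prevalence", "deaths", "yll", "yld")

  # pool sexes by summing counts and populations
  both <- noisy %>%
    group_by(.data$location_id, .data$year, .data$age_group) %>%
    summarise(across(c("population", "incidence", "prevalence", "deaths",
                       "yll", "yld"), sum), .groups = "drop") %>%
    mutate(sex = "both")
  band_level <- bind_rows(noisy, both)

  long <- band_level %>%
    tidyr::pivot_longer(c("incidence", "prevalence", "deaths", "yll", "yld"),
                        names_to = "measure", values_to = "count")

  counts_bands <- long %>%
    mutate(metric = "count", value = .data$count) %>%
    select("location_id", "year", "sex", "age_group", "measure", "metric", "value")
  rates_bands <- long %>%
    mutate(metric = "rate_per_100k", value = .data$count / .data$population * 1e5) %>%
    select("location_id", "year", "sex", "age_group", "measure", "metric", "value")

  all_ages <- long %>%
    group_by(.data$location_id, .data$year, .data$sex, .data$measure) %>%
    summarise(count = sum(.data$count), population = sum(.data$population),
              .groups = "drop")
  counts_all <- all_ages %>%
    mutate(age_group = "all_ages", metric = "count", value = .data$count) %>%
    select("location_id", "year", "sex", "age_group", "measure", "metric", "value")
  rates_all <- all_ages %>%
    mutate(age_group = "all_ages", metric = "rate_per_100k",
           value = .data$count / .data$population * 1e5) %>%
    select("location_id", "year", "sex", "age_group", "measure", "metric", "value")

  w <- unclass(std_pop)[bands]
  rates_std <- long %>%
    mutate(w = .env$w[.data$age_group]) %>%
    group_by(.data$location_id, .data$year, .data$sex, .data$measure) %>%
    summarise(value = sum(.data$w * .data$count / .data$population * 1e5),
              .groups = "drop") %>%
    mutate(age_group = "age_standardized", metric = "rate_per_100k") %>%
    select("location_id", "year", "sex", "age_group", "measure", "metric", "value")

  panel5 <- bind_rows(counts_bands, rates_bands, counts_all, rates_all, rates_std)

  # DALY as the exact post-noise sum of YLL and YLD in every stratum
  daly <- panel5 %>%
    filter(.data$measure %in% c("yll", "yld")) %>%
    tidyr::pivot_wider(names_from = "measure", values_from = "value") %>%
    mutate(measure = "daly", value = .data$yll + .data$yld) %>%
    select("location_id", "year", "sex", "age_group", "measure", "metric", "value")

  panel <- bind_rows(panel5, daly) %>%
    mutate(
      location_name = .data$location_id,
      lower = .data$value * (1 - config$ui_halfwidth_frac),
      upper = .data$value * (1 + config$ui_halfwidth_frac)
    ) %>%
    select(all_of(panel_columns())) %>%
    arrange(.data$location_id, .data$year, .data$sex, .data$age_group,
            .data$measure, .data$metric)
  validate_panel(panel)
  panel
}

#' Generate a HAQ-like external reference index
#'
#' A monotone affine transform of latent quality plus Gaussian noise,
#' min-max rescaled to 0-100 across all (location, year) cells. Serves as
#' the synthetic counterpart of an external healthcare access and quality
#' index for validity checks.
#'
#' @param world A [generate_world()] result.
#' @param noise_sd SD of the additive noise on the latent-quality scale.
#' @return Tibble `location_id, year, reference_index`.
#' @export
generate_reference_index <- function(world, noise_sd = 0.05) {
  stopifnot(inherits(world, "synthetic_world"))
  config <- world$config
  set.seed(config$seed + 2L)
  grid <- tidyr::expand_grid(location_id = world$countries$location_id,
                             year = config$years) %>%
    left_join(select(world$countries, "location_id", "latent_quality"),
              by = "location_id") %>%
    mutate(raw = .data$latent_quality + rnorm(dplyr::n(), 0, noise_sd))
  rng <- range(grid$raw)
  if (diff(rng) == 0) {
    grid$reference_index <- rep(50, nrow(grid))
  } else {
    grid$reference_index <- 100 * (grid$raw - rng[1]) / diff(rng)
  }
  select(grid, "location_id", "year", "reference_index")
}

#' Generate healthcare utilization covariates
#'
#' Positive inpatient and outpatient utilization rates, log-linear in SDI
#' with lognormal noise; deterministic given the world's seed.
#'
#' @param world A [generate_world()] result.
#' @param noise_sd SD of the log-scale noise (0 gives rank equality with
#'   SDI).
#' @return Tibble `location_id, year, inpatient_utilization,
#'   outpatient_utilization`.
#' @export
generate_utilization_covariates <- function(world, noise_sd = 0.1) {
  stopifnot(inherits(world, "synthetic_world"))
  config <- world$config
  set.seed(config$seed + 3L)
  tidyr::expand_grid(location_id = world$countries$location_id,
                     year = config$years) %>%
    left_join(select(world$countries, "location_id", "sdi"), by = "location_id") %>%
    mutate(
      inpatient_utilization = exp(1.0 + 1.2 * .data$sdi +
                                    rnorm(dplyr::n(), 0, noise_sd)),
      outpatient_utilization = exp(2.0 + 1.5 * .data$sdi +
                                     rnorm(dplyr::n(), 0, noise_sd))
    ) %>%
    select("location_id", "year", "inpatient_utilization", "outpatient_utilization")
}
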