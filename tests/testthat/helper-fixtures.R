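# Shared fixtures, built in code and cached across test files.

.sim_cache <- new.env(parent = emptyenv())

# The study-scale synthetic world: 100 countries x 1990-2017 (the default
# generator conditions). Built once; used by the end-to-end recovery tests.
default_sim <- function(seed = 1L) {
  key <- paste0("default_", seed)
  if (is.null(.sim_cache[[key]])) {
    cfg <- synthetic_config(seed = seed)
    world <- generate_world(cfg)
    panel <- generate_epi_panel(world)
    ratios <- compute_secondary_ratios(panel)
    model <- fit_qci_model(ratios)
    .sim_cache[[key]] <- list(cfg = cfg, world = world, panel = panel,
                              ratios = ratios, model = model,
                              qci = score_quartets(ratios, model))
  }
  .sim_cache[[key]]
}

# A small, fast world for unit tests: 20 countries x 6 years.
small_sim <- function(seed = 42L) {
  key <- paste0("small_", seed)
  if (is.null(.sim_cache[[key]])) {
    cfg <- synthetic_config(n_countries = 20, years = 2000:2005, seed = seed)
    world <- generate_world(cfg)
    panel <- generate_epi_panel(world)
    ratios <- compute_secondary_ratios(panel)
    model <- fit_qci_model(ratios)
    .sim_cache[[key]] <- list(cfg = cfg, world = world, panel = panel,
                              ratios = ratios, model = model,
                              qci = score_quartets(ratios, model))
  }
  .sim_cache[[key]]
}

# A hand-built 6-row valid panel (one stratum, all six measures).
toy_panel <- function() {
  tibble::tibble(
    location_id = "AFG", location_name = "AFG", year = 2017L,
    sex = "both", age_group = "age_standardized",
    measure = c("incidence", "prevalence", "deaths", "daly", "yll", "yld"),
    metric = "rate_per_100k",
    value = c(5.16, 22.01, 3.11, 111.91, 109.78, 2.13),
    lower = c(4.46, 18.96, 2.68, 95.69, 96.10, 1.49),
    upper = c(5.63, 24.47, 3.34, 151.42, 120.04, 2.85)
  )
}

# Random valid panel for round-trip tests.
random_panel <- function(n = 100, seed = 7) {
  set.seed(seed)
  value <- runif(n, 0, 100)
  tibble::tibble(
    location_id = sample(sprintf("L%02d", 1:8), n, replace = TRUE),
    year = sample(1990:2017, n, replace = TRUE),
    sex = sample(epi_sexes(), n, replace = TRUE),
    age_group = sample(c(age_bands(), "all_ages"), n, replace = TRUE),
    measure = sample(epi_measures(), n, replace = TRUE),
    metric = sample(epi_metrics(), n, replace = TRUE),
    value = value,
    lower = value * 0.9,
    upper = value * 1.1
  ) |>
    dplyr::distinct(measure, metric, location_id, year, sex, age_group,
                    .keep_all = TRUE) |>
    dplyr::mutate(location_name = location_id, .after = location_id)
}
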