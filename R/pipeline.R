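# End-to-end orchestration: config-driven run from a (synthetic or supplied)
# burden panel to QCI / GDR / age-disparity / significance / validation tables.

#' Run configuration
#'
#' @param input_mode `"synthetic"` (generate a panel from `synthetic`) or
#'   `"file"` (read `panel_path` with [read_panel()]).
#' @param synthetic A [synthetic_config()] (synthetic mode). Its seed is
#'   overridden by `seed`.
#' @param panel_path Path to a panel CSV (file mode).
#' @param dialect CSV dialect for file mode.
#' @param years Optional year filter for the reference fit and all outputs.
#' @param scoring_mode `"fit_pca"` (fit first-component loadings on the
#'   reference set) or `"fixed_coefficients"` (use [published_loadings()]).
#' @param age_scheme An [age_group_scheme()].
#' @param output_dir Directory for output tables (created if needed).
#' @param seed Integer master seed, recorded in every output.
#' @return List of class `run_config`.
#' @export
run_config <- function(input_mode = c("synthetic", "file"),
                       synthetic = synthetic_config(),
                       panel_path = NULL,
                       dialect = "gbd",
                       years = NULL,
                       scoring_mode = c("fit_pca", "fixed_coefficients"),
                       age_scheme = age_group_scheme(),
                       output_dir = tempfile("qci_run_"),
                       seed = 20170L) {
  input_mode <- match.arg(input_mode)
  scoring_mode <- match.arg(scoring_mode)
  if (input_mode == "file" && is.null(panel_path)) {
    abort("`panel_path` is required in file mode.", class = "qcindex_config_error")
  }
  if (input_mode == "synthetic") {
    synthetic$seed <- as.integer(seed)
  }
  structure(list(
    input_mode = input_mode, synthetic = synthetic, panel_path = panel_path,
    dialect = dialect, years = years, scoring_mode = scoring_mode,
    age_scheme = age_scheme, output_dir = output_dir, seed = as.integer(seed)
  ), class = "run_config")
}

#' Serialize / restore a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  payload <- unclass(config)
  payload$synthetic <- lapply(unclass(payload$synthetic), function(x) {
    if (!is.null(names(x))) as.list(x) else x
  })
  payload$age_scheme <- unclass(payload$age_scheme)
  yaml::write_yaml(payload, path, precision = 17)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  p <- yaml::read_yaml(path)
  syn <- p$synthetic
  config <- run_config(
    input_mode = p$input_mode,
    synthetic = synthetic_config(
      n_countries = syn$n_countries, years = unlist(syn$years),
      age_bands_used = unlist(syn$age_bands_used), seed = syn$seed,
      sdi_range = unlist(syn$sdi_range),
      quality_sdi_slope = syn$quality_sdi_slope,
      quality_noise_sd = syn$quality_noise_sd,
      gender_gap_base = syn$gender_gap_base,
      gender_gap_sdi_slope = syn$gender_gap_sdi_slope,
      baseline_incidence_per_100k = syn$baseline_incidence_per_100k,
      incidence_age_profile = unlist(syn$incidence_age_profile),
      mir_logistic_params = unlist(syn$mir_logistic_params),
      survival_years_params = unlist(syn$survival_years_params),
      disability_weight = syn$disability_weight,
      residual_life_expectancy = unlist(syn$residual_life_expectancy),
      noise_cv = syn$noise_cv, ui_halfwidth_frac = syn$ui_halfwidth_frac,
      population_lognormal = unlist(syn$population_lognormal)
    ),
    panel_path = p$panel_path, dialect = p$dialect,
    years = if (is.null(p$years)) NULL else unlist(p$years),
    scoring_mode = p$scoring_mode,
    age_scheme = age_group_scheme(p$age_scheme$childhood_max,
                                  p$age_scheme$elderly_min),
    output_dir = p$output_dir, seed = p$seed
  )
  config
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("[stage: ", stage, "] ", conditionMessage(e)),
          class = "qcindex_stage_error", parent = e)
  })
}

global_burden_summary <- function(panel) {
  # A panel-wide "global" aggregate per (measure, metric, year): counts (and
  # their interval bounds) are summed over locations; age-standardized rates
  # are averaged over locations. Used only for the between-year significance
  # table when the panel carries no explicit Global location.
  if ("Global" %in% panel$location_id) {
    return(panel %>%
             filter(.data$location_id == "Global", .data$sex == "both",
                    .data$age_group %in% c("all_ages", "age_standardized")) %>%
             filter((.data$metric == "count" & .data$age_group == "all_ages") |
                      (.data$metric == "rate_per_100k" &
                         .data$age_group == "age_standardized")) %>%
             select("measure", "metric", "year", "value", "lower", "upper"))
  }
  counts <- panel %>%
    filter(.data$sex == "both", .data$age_group == "all_ages",
           .data$metric == "count") %>%
    group_by(.data$measure, .data$metric, .data$year) %>%
    summarise(across(c("value", "lower", "upper"), sum), .groups = "drop")
  rates <- panel %>%
    filter(.data$sex == "both", .data$age_group == "age_standardized",
           .data$metric == "rate_per_100k") %>%
    group_by(.data$measure, .data$metric, .data$year) %>%
    summarise(across(c("value", "lower", "upper"), mean), .groups = "drop")
  bind_rows(counts, rates)
}

#' Run the full QCI study pipeline
#'
#' Generates or reads a burden panel, fits (or fixes) the scoring model on
#' both-sex age-standardized country-year ratios, and writes the report
#' tables: `qci_by_location_year.csv`, `qci_by_sex.csv`, `gdr.csv` (with
#' outlier flags), `qci_by_age_group.csv`, a first-vs-last-year
#' interval-overlap significance table, `model.yaml`, `validation.yaml`
#' (synthetic mode), a config echo and a run log. Identical configurations
#' produce identical outputs.
#'
#' @param config A [run_config()].
#' @return The output directory path, invisibly; the fitted model and main
#'   tables are attached as attributes `model`, `qci`, `gdr`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  log_lines <- c(sprintf("qcindex run (seed %d, mode %s, scoring %s)",
                         config$seed, config$input_mode, config$scoring_mode))

  world <- NULL
  if (config$input_mode == "synthetic") {
    world <- with_stage("generate_world", generate_world(config$synthetic))
    panel <- with_stage("generate_panel", generate_epi_panel(world))
  } else {
    panel <- with_stage("read_panel", read_panel(config$panel_path, config$dialect))
  }
  years_used <- if (is.null(config$years)) sort(unique(panel$year)) else config$years
  log_lines <- c(log_lines, sprintf("panel: %d rows, years %d-%d",
                                    nrow(panel), min(years_used), max(years_used)))

  ratios <- with_stage("secondary_ratios",
    compute_secondary_ratios(panel, years = years_used))
  excluded <- attr(ratios, "excluded")
  if (!is.null(excluded) && nrow(excluded) > 0) {
    log_lines <- c(log_lines, sprintf("excluded strata (zero denominators): %d",
                                      nrow(excluded)),
                   paste(" -", excluded$location_id, excluded$year))
  }
  model <- with_stage("fit_model", fit_qci_model(
    ratios,
    loadings = if (config$scoring_mode == "fixed_coefficients")
      published_loadings() else NULL
  ))
  write_qci_model(model, out("model.yaml"))

  qci_both <- with_stage("score", score_quartets(ratios, model))
  readr::write_csv(qci_both %>% mutate(seed = config$seed), out("qci_by_location_year.csv"),
                   progress = FALSE)

  qci_sex <- with_stage("score_by_sex", compute_qci(
    panel, model, sexes = c("female", "male"), years = years_used))
  readr::write_csv(qci_sex %>% mutate(seed = config$seed), out("qci_by_sex.csv"),
                   progress = FALSE)

  gdr <- with_stage("gdr", compute_gdr_table(panel, model, years = years_used))
  readr::write_csv(gdr %>% mutate(seed = config$seed), out("gdr.csv"), progress = FALSE)

  qci_age <- with_stage("age_groups", qci_by_age_group(
    panel, model, scheme = config$age_scheme,
    sexes = c("both", "female", "male"), years = years_used))
  readr::write_csv(qci_age %>% mutate(seed = config$seed), out("qci_by_age_group.csv"),
                   progress = FALSE)

  y1 <- min(years_used); y2 <- max(years_used)
  signif_tab <- with_stage("significance", {
    gb <- global_burden_summary(filter(panel, .data$year %in% c(y1, y2)))
    compare_years_significance(gb, y1, y2)
  })
  readr::write_csv(signif_tab, out(sprintf("significance_%d_vs_%d.csv", y1, y2)),
                   progress = FALSE)

  if (config$input_mode == "synthetic") {
    quintiles <- assign_sdi_quintiles(
      select(world$countries, "location_id", "sdi"))
    prev_counts <- panel %>%
      filter(.data$measure == "prevalence", .data$metric == "count",
             .data$sex == "both", .data$age_group == "all_ages") %>%
      select("location_id", "year", prevalence_count = "value")
    qci_grouped <- qci_both %>%
      left_join(select(quintiles, "location_id", "sdi_quintile"), by = "location_id") %>%
      left_join(prev_counts, by = c("location_id", "year"))
    sdi_summary <- summarize_by_group(qci_grouped, "sdi_quintile",
                                      weight_col = "prevalence_count")
    readr::write_csv(sdi_summary, out("qci_summary_by_sdi_quintile.csv"),
                     progress = FALSE)

    validation <- with_stage("validation", {
      reference <- generate_reference_index(world)
      covars <- generate_utilization_covariates(world) %>%
        left_join(
          panel %>%
            filter(.data$metric == "rate_per_100k", .data$sex == "both",
                   .data$age_group == "age_standardized",
                   .data$measure %in% c("deaths", "prevalence")) %>%
            select("location_id", "year", "measure", "value") %>%
            tidyr::pivot_wider(names_from = "measure", values_from = "value") %>%
            rename(deaths_rate = "deaths", prevalence_rate = "prevalence"),
          by = c("location_id", "year")
        )
      validate_against_reference(
        select(qci_both, "location_id", "year", "qci"), reference, covars)
    })
    yaml::write_yaml(list(
      fixed_effects = purrr::transpose(as.list(validation$fixed_effects)),
      random_intercept_variance = validation$random_intercept_variance,
      residual_variance = validation$residual_variance,
      pearson_r_with_reference = validation$pearson_r_with_reference,
      n_observations = validation$n_observations,
      n_groups = validation$n_groups,
      seed = config$seed
    ), out("validation.yaml"), precision = 17)
    log_lines <- c(log_lines, sprintf(
      "validation: r(QCI, reference) = %.4f over %d country-years",
      validation$pearson_r_with_reference, validation$n_observations))
  }

  write_run_config(config, out("config.yaml"))
  writeLines(log_lines, out("run.log"))
  structure(invisible(config$output_dir),
            model = model, qci = qci_both, gdr = gdr)
}

#' Weighted group summaries of QCI
#'
#' Weighted mean QCI per group. Weights default to equal; the intended
#' population weighting uses prevalence counts.
#'
#' @param qci_table A tibble with a `qci` column and (except for
#'   `grouping = "global"`) a column named after the grouping.
#' @param grouping One of `"global"`, `"sdi_quintile"`, `"region"`,
#'   `"location"`.
#' @param weight_col Optional name of a weight column.
#' @return Tibble with one row per group: `mean_qci`, `n`.
#' @export
summarize_by_group <- function(qci_table,
                               grouping = c("global", "sdi_quintile",
                                            "region", "location"),
                               weight_col = NULL) {
  grouping <- tryCatch(match.arg(grouping), error = function(e)
    abort("Unknown grouping.", class = "qcindex_domain_error"))
  key <- switch(grouping, global = NULL, sdi_quintile = "sdi_quintile",
                region = "region", location = "location_id")
  if (!is.null(key) && !key %in% names(qci_table)) {
    abort(paste0("Grouping column `", key, "` not present."),
          class = "qcindex_domain_error")
  }
  tab <- qci_table
  tab$.w <- if (is.null(weight_col)) rep(1, nrow(tab)) else tab[[weight_col]]
  grouped <- if (is.null(key)) tab %>% mutate(group = "global") %>% group_by(.data$group)
  else tab %>% group_by(group = .data[[key]])
  grouped %>%
    summarise(mean_qci = sum(.data$qci * .data$.w) / sum(.data$.w),
              n = dplyr::n(), .groups = "drop")
}
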