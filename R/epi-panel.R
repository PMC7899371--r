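# Canonical vocabularies for long-format burden panels.

#' Measure, metric and sex vocabularies
#'
#' Canonical levels used throughout the package for the six primary burden
#' measures, the two reporting metrics, and the sex strata of a panel.
#'
#' @return A character vector of canonical level names.
#' @export
epi_measures <- function() c("incidence", "prevalence", "deaths", "daly", "yll", "yld")

#' @rdname epi_measures
#' @export
epi_metrics <- function() c("count", "rate_per_100k")

#' @rdname epi_measures
#' @export
epi_sexes <- function() c("female", "male", "both")

#' Five-year age bands covering 0 to 95+
#'
#' The default fine age grid: twenty 5-year bands `"0-4"` ... `"90-94"`,
#' `"95+"`. Panels may additionally carry the aggregate pseudo-bands
#' `"all_ages"` and `"age_standardized"` and the coarse groups `"childhood"`,
#' `"adulthood"`, `"elderly"`.
#'
#' @return Character vector of 20 band labels.
#' @export
age_bands <- function() {
  c(paste(seq(0, 90, by = 5), seq(4, 94, by = 5), sep = "-"), "95+")
}

#' @rdname age_bands
#' @export
age_band_start <- function(band) {
  suppressWarnings(as.numeric(sub("[-+].*$", "", band)))
}

aggregate_age_groups <- function() c("all_ages", "age_standardized")
coarse_age_groups <- function() c("childhood", "adulthood", "elderly")

panel_columns <- function() {
  c("location_id", "location_name", "year", "sex", "age_group",
    "measure", "metric", "value", "lower", "upper")
}

# ---------------------------------------------------------------------------
# Validation

#' Validate a long-format burden panel
#'
#' Checks the panel invariants: required columns present; `value >= 0`;
#' `lower <= value <= upper`; measure/metric/sex levels drawn from the
#' canonical vocabularies; and one row per
#' (measure, metric, location, year, sex, age_group) key.
#'
#' @param panel A data frame with the columns of [read_panel()] output.
#' @return The panel, invisibly, if valid. Otherwise an error of class
#'   `qcindex_validation_error` reporting the offending row indices.
#' @export
validate_panel <- function(panel) {
  missing_cols <- setdiff(panel_columns(), names(panel))
  if (length(missing_cols) > 0) {
    abort(paste0("Panel is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "qcindex_format_error")
  }
  bad_value <- which(!is.finite(panel$value) | panel$value < 0)
  bad_ui <- which(is.finite(panel$lower) & is.finite(panel$upper) &
                    (panel$lower > panel$value | panel$value > panel$upper))
  bad_level <- which(!(panel$measure %in% epi_measures()) |
                       !(panel$metric %in% epi_metrics()) |
                       !(panel$sex %in% epi_sexes()))
  dup <- which(duplicated(panel[, c("measure", "metric", "location_id",
                                    "year", "sex", "age_group")]))
  problems <- list(
    "negative or non-finite value" = bad_value,
    "uncertainty interval does not bracket value (lower <= value <= upper)" = bad_ui,
    "unknown measure/metric/sex level" = bad_level,
    "duplicate (measure, metric, location, year, sex, age_group) key" = dup
  )
  problems <- problems[lengths(problems) > 0]
  if (length(problems) > 0) {
    msg <- vapply(seq_along(problems), function(i) {
      idx <- problems[[i]]
      shown <- paste(head(idx, 10), collapse = ", ")
      if (length(idx) > 10) shown <- paste0(shown, ", ... (", length(idx), " rows)")
      paste0(names(problems)[i], ": rows ", shown)
    }, character(1))
    abort(c("Invalid burden panel.", msg), class = "qcindex_validation_error")
  }
  invisible(panel)
}

# ---------------------------------------------------------------------------
# I/O

gbd_measure_synonyms <- function(x) {
  x <- tolower(trimws(x))
  x <- sub(" \\(.*\\)$", "", x)           # e.g. "dalys (disability-adjusted life years)"
  dplyr::recode(x,
    "death" = "deaths", "dalys" = "daly", "ylls" = "yll", "ylds" = "yld",
    .default = x
  )
}

gbd_metric_synonyms <- function(x) {
  x <- tolower(trimws(x))
  dplyr::recode(x,
    "number" = "count",
    "rate" = "rate_per_100k",
    "rate per 100,000" = "rate_per_100k",
    .default = x
  )
}

#' Read a long-format burden panel from CSV
#'
#' Reads a GBD-results-style CSV (columns `measure, location, sex, age, year,
#' metric, val, upper, lower`, in any order) or the package's canonical
#' dialect (columns as in [validate_panel()]), normalizes vocabulary
#' (e.g. `Number` -> `count`, `Deaths` -> `deaths`), and validates all panel
#' invariants before returning.
#'
#' @param source Path to a CSV file.
#' @param dialect `"gbd"` (default) or `"canonical"`.
#' @return A validated tibble with columns `location_id, location_name, year,
#'   sex, age_group, measure, metric, value, lower, upper`.
#' @seealso [write_panel()]
#' @export
read_panel <- function(source, dialect = c("gbd", "canonical")) {
  dialect <- match.arg(dialect)
  if (!file.exists(source)) {
    abort(paste0("Panel file does not exist: ", source), class = "qcindex_format_error")
  }
  raw <- readr::read_csv(source, show_col_types = FALSE, progress = FALSE)
  if (dialect == "gbd") {
    required <- c("measure", "location", "sex", "age", "year", "metric",
                  "val", "upper", "lower")
    missing_cols <- setdiff(required, names(raw))
    if (length(missing_cols) > 0) {
      abort(paste0("Missing required column(s) for the 'gbd' dialect: ",
                   paste(missing_cols, collapse = ", ")),
            class = "qcindex_format_error")
    }
    panel <- tibble(
      location_id = as.character(raw$location),
      location_name = as.character(raw$location),
      year = as.integer(raw$year),
      sex = tolower(trimws(as.character(raw$sex))),
      age_group = as.character(raw$age),
      measure = gbd_measure_synonyms(as.character(raw$measure)),
      metric = gbd_metric_synonyms(as.character(raw$metric)),
      value = as.numeric(raw$val),
      lower = as.numeric(raw$lower),
      upper = as.numeric(raw$upper)
    )
  } else {
    missing_cols <- setdiff(panel_columns(), names(raw))
    if (length(missing_cols) > 0) {
      abort(paste0("Missing required column(s) for the 'canonical' dialect: ",
                   paste(missing_cols, collapse = ", ")),
            class = "qcindex_format_error")
    }
    panel <- as_tibble(raw[, panel_columns()])
    panel$year <- as.integer(panel$year)
    for (col in c("location_id", "location_name", "sex", "age_group", "measure", "metric")) {
      panel[[col]] <- as.character(panel[[col]])
    }
  }
  validate_panel(panel)
  panel
}

#' Write a burden panel to CSV
#'
#' Writes the GBD-results-style dialect that [read_panel()] reads back, with
#' full-precision numeric fields so that `read_panel(write_panel(p))` is the
#' identity on valid panels.
#'
#' @param panel A validated panel tibble.
#' @param dest Output file path.
#' @return `dest`, invisibly.
#' @export
write_panel <- function(panel, dest) {
  validate_panel(panel)
  out <- tibble(
    measure = panel$measure,
    location = panel$location_id,
    sex = panel$sex,
    age = panel$age_group,
    year = panel$year,
    metric = panel$metric,
    val = panel$value,
    upper = panel$upper,
    lower = panel$lower
  )
  readr::write_csv(out, dest, progress = FALSE)
  invisible(dest)
}

# ---------------------------------------------------------------------------
# Rates and age-standardization

#' Crude rate per 100,000
#'
#' @param count Non-negative event count (vectorized).
#' @param population Person denominator, strictly positive.
#' @return `count / population * 1e5`.
#' @export
crude_rate <- function(count, population) {
  if (any(!is.finite(population) | population <= 0)) {
    abort("`population` must be strictly positive.", class = "qcindex_domain_error")
  }
  if (any(!is.finite(count) | count < 0)) {
    abort("`count` must be non-negative.", class = "qcindex_domain_error")
  }
  count / population * 1e5
}

#' Construct a standard population
#'
#' A set of non-negative age-band weights summing to one (within 1e-9),
#' used for direct age-standardization.
#'
#' @param weights Named numeric vector: age band -> proportion.
#' @return An object of class `standard_population` (a named numeric vector).
#' @export
standard_population <- function(weights) {
  if (is.data.frame(weights)) {
    weights <- setNames(weights$weight, weights$age_group)
  }
  if (is.null(names(weights)) || any(names(weights) == "")) {
    abort("Standard population weights must be named by age band.",
          class = "qcindex_domain_error")
  }
  if (any(weights < 0)) {
    abort("Standard population weights must be non-negative.",
          class = "qcindex_domain_error")
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    abort(sprintf("Standard population weights must sum to 1 (got %.12f).",
                  sum(weights)), class = "qcindex_domain_error")
  }
  structure(weights, class = c("standard_population", "numeric"))
}

#' Directly age-standardized rate per 100,000
#'
#' Computes `sum_a w_a * (count_a / pop_a) * 1e5` over aligned age bands.
#'
#' @param counts Named numeric vector of event counts by age band.
#' @param populations Named numeric vector of person counts by age band.
#' @param std_pop A [standard_population()] (or a named vector of weights
#'   summing to one) covering every band in `counts`.
#' @return The age-standardized rate (scalar).
#' @export
age_standardize <- function(counts, populations, std_pop) {
  if (!inherits(std_pop, "standard_population")) std_pop <- standard_population(std_pop)
  bands <- names(counts)
  missing_pop <- setdiff(bands, names(populations))
  missing_w <- setdiff(bands, names(std_pop))
  if (length(missing_pop) > 0 || length(missing_w) > 0) {
    abort(paste0("Age bands not covered: ",
                 paste(union(missing_pop, missing_w), collapse = ", ")),
          class = "qcindex_alignment_error")
  }
  rates <- crude_rate(counts, populations[bands])
  sum(unclass(std_pop)[bands] * rates)
}

# ---------------------------------------------------------------------------
# Uncertainty-interval overlap rule

#' Non-overlap significance of two uncertainty intervals
#'
#' Two estimates are called significantly different when their 95%
#' uncertainty intervals do not overlap. Closed intervals touching at a
#' single endpoint are treated as overlapping (not significant).
#'
#' @param a,b Numeric length-2 vectors `c(lower, upper)`.
#' @return `TRUE` if the intervals are disjoint (significant difference).
#' @export
ui_overlap_significant <- function(a, b) {
  check_interval <- function(x, label) {
    if (length(x) != 2 || any(!is.finite(x)) || x[1] > x[2]) {
      abort(paste0("`", label, "` must be a finite interval c(lower, upper) with lower <= upper."),
            class = "qcindex_domain_error")
    }
  }
  check_interval(a, "a")
  check_interval(b, "b")
  unname(a[2] < b[1] || b[2] < a[1])
}

#' Interval-overlap significance between two years of a burden table
#'
#' For every (measure, metric) present in both years, applies
#' [ui_overlap_significant()] to the pair of 95% uncertainty intervals.
#'
#' @param burden Tibble with columns `measure, metric, year, value, lower,
#'   upper` (e.g. [cns_global_burden()]).
#' @param year_a,year_b The two years to compare.
#' @return Tibble with one row per (measure, metric) and a logical
#'   `significant` column.
#' @export
compare_years_significance <- function(burden, year_a, year_b) {
  a <- filter(burden, .data$year == year_a)
  b <- filter(burden, .data$year == year_b)
  joined <- inner_join(a, b, by = c("measure", "metric"), suffix = c("_a", "_b"))
  if (nrow(joined) == 0) {
    abort("No (measure, metric) pairs shared between the two years.",
          class = "qcindex_data_error")
  }
  joined %>%
    mutate(significant = purrr::map2_lgl(
      purrr::map2(.data$lower_a, .data$upper_a, c),
      purrr::map2(.data$lower_b, .data$upper_b, c),
      ui_overlap_significant
    )) %>%
    select("measure", "metric",
           value_a = "value_a", lower_a = "lower_a", upper_a = "upper_a",
           value_b = "value_b", lower_b = "lower_b", upper_b = "upper_b",
           "significant") %>%
    mutate(year_a = year_a, year_b = year_b, .before = 1)
}
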