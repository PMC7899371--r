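#' Global burden of brain and other CNS cancers, 1990 and 2017
#'
#' Published global estimates (GBD 2017) of prevalence, incidence, deaths,
#' DALYs, YLDs and YLLs for brain and other central nervous system cancers:
#' counts (persons or person-years) and age-standardized rates per 100,000,
#' each with its 95% uncertainty interval, for 1990 and 2017. Useful as a
#' small real-data input for the interval-overlap significance rule and for
#' worked examples.
#'
#' @return Tibble with columns `measure, metric, year, value, lower, upper`
#'   (24 rows: 6 measures x 2 metrics x 2 years). Counts are raw (not
#'   thousands).
#' @export
cns_global_burden <- function() {
  k <- 1e3
  tibble::tribble(
    ~measure,     ~metric,         ~year, ~value,     ~lower,     ~upper,
    "prevalence", "count",          1990, 630 * k,    512 * k,    762 * k,
    "prevalence", "rate_per_100k",  1990, 12.35,      10.28,      14.76,
    "incidence",  "count",          1990, 194 * k,    159 * k,    233 * k,
    "incidence",  "rate_per_100k",  1990, 3.97,       3.32,       4.71,
    "deaths",     "count",          1990, 142 * k,    117 * k,    170 * k,
    "deaths",     "rate_per_100k",  1990, 3.03,       2.56,       3.58,
    "daly",       "count",          1990, 6368 * k,   4836 * k,   7987 * k,
    "daly",       "rate_per_100k",  1990, 111.91,     97.82,      122.53,
    "yld",        "count",          1990, 71 * k,     48 * k,     95 * k,
    "yld",        "rate_per_100k",  1990, 1.43,       0.99,       1.91,
    "yll",        "count",          1990, 6297 * k,   4770 * k,   7914 * k,
    "yll",        "rate_per_100k",  1990, 121.13,     94.53,      149.67,
    "prevalence", "count",          2017, 1700 * k,   1470 * k,   1890 * k,
    "prevalence", "rate_per_100k",  2017, 22.01,      18.96,      24.47,
    "incidence",  "count",          2017, 405 * k,    351 * k,    442 * k,
    "incidence",  "rate_per_100k",  2017, 5.16,       4.46,       5.63,
    "deaths",     "count",          2017, 247 * k,    212 * k,    265 * k,
    "deaths",     "rate_per_100k",  2017, 3.11,       2.68,       3.34,
    "daly",       "count",          2017, 8744 * k,   7652 * k,   9554 * k,
    "daly",       "rate_per_100k",  2017, 122.57,     95.69,      151.42,
    "yld",        "count",          2017, 167 * k,    117 * k,    223 * k,
    "yld",        "rate_per_100k",  2017, 2.13,       1.49,       2.85,
    "yll",        "count",          2017, 8577 * k,   7527 * k,   9359 * k,
    "yll",        "rate_per_100k",  2017, 109.78,     96.10,      120.04
  )
}

#' World standard population weights
#'
#' GBD-style world standard population proportions on the twenty 5-year
#' bands of [age_bands()], read from the versioned file bundled under
#' `inst/extdata/` and normalized to sum exactly to one. Any
#' [standard_population()] summing to one is accepted by
#' [age_standardize()]; this is the default used by the synthetic generator
#' and the pipeline.
#'
#' @return A [standard_population()] named by age band.
#' @export
world_standard_population <- function() {
  path <- system.file("extdata", "world_standard_population.csv",
                      package = "qcindex", mustWork = TRUE)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  w <- setNames(tab$proportion_percent, tab$age_group)
  standard_population(w / sum(w))
}
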