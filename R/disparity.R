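# Gender and age inequity analytics on top of a fitted QCI model.

#' Coarse age-group scheme
#'
#' Childhood / adulthood / elderly boundaries. By default childhood is ages
#' below 20, adulthood 20-65, elderly above 65; a 5-year band is assigned by
#' its lower bound (so `65-69` falls in `elderly`). An alternative scheme
#' (e.g. an 18-year childhood cut) can be configured as long as no 5-year
#' band straddles a boundary under the lower-bound rule.
#'
#' @param childhood_max First age (in years) no longer counted as
#'   childhood.
#' @param elderly_min First band lower bound counted as elderly.
#' @return List of class `age_group_scheme`.
#' @export
age_group_scheme <- function(childhood_max = 20, elderly_min = 65) {
  if (!(childhood_max < elderly_min)) {
    abort("`childhood_max` must be below `elderly_min`.", class = "qcindex_domain_error")
  }
  structure(list(childhood_max = childhood_max, elderly_min = elderly_min),
            class = "age_group_scheme")
}

#' Assign a fine age band to a coarse age group
#'
#' @param band Character vector of 5-year band labels (e.g. `"15-19"`,
#'   `"95+"`).
#' @param scheme An [age_group_scheme()].
#' @return Character vector in `{childhood, adulthood, elderly}`.
#' @export
assign_age_group <- function(band, scheme = age_group_scheme()) {
  stopifnot(inherits(scheme, "age_group_scheme"))
  start <- age_band_start(band)
  if (any(is.na(start))) {
    abort(paste0("Unknown age band(s): ",
                 paste(unique(band[is.na(start)]), collapse = ", ")),
          class = "qcindex_domain_error")
  }
  case_when(
    start < scheme$childhood_max ~ "childhood",
    start < scheme$elderly_min ~ "adulthood",
    TRUE ~ "elderly"
  )
}

#' Gender Disparity Ratio
#'
#' `GDR = QCI_female / QCI_male`; 1 means gender parity, values below 1
#' male-favoring care. Vectorized.
#'
#' @param qci_female,qci_male QCI values in `[0, 100]`; `qci_male` must be
#'   strictly positive.
#' @return Positive ratio(s).
#' @export
compute_gdr <- function(qci_female, qci_male) {
  if (any(!is.finite(qci_male)) || any(qci_male <= 0)) {
    bad <- which(!is.finite(qci_male) | qci_male <= 0)
    abort(c("Undefined GDR: male QCI is zero (or non-finite).",
            paste0("Offending element(s): ", paste(head(bad, 10), collapse = ", "))),
          class = "qcindex_undefined_gdr_error")
  }
  if (any(!is.finite(qci_female) | qci_female < 0)) {
    abort("`qci_female` must be finite and non-negative.",
          class = "qcindex_domain_error")
  }
  qci_female / qci_male
}

#' Female-to-male QCI ratios across a panel
#'
#' Scores each sex separately under the fixed both-sex reference model
#' (same means, SDs, loadings and rescaling bounds, clipped to `[0, 100]`,
#' so sexes share one scale), joins them per (location, year, age_group),
#' and computes the GDR with leave-one-out outlier flags per (year,
#' age_group) across locations. Strata with male QCI equal to 0 have an
#' undefined GDR and are dropped with a warning (listed in the `dropped`
#' attribute).
#'
#' @param panel A validated burden panel containing `female` and `male`
#'   rows.
#' @param model The both-sex reference [fit_qci_model()].
#' @param metric,age_groups,years Passed to [compute_qci()].
#' @param outlier_k SD multiplier for [flag_outliers()] (default 3).
#' @return Tibble `location_id, year, age_group, qci_female, qci_male, gdr,
#'   outlier`.
#' @export
compute_gdr_table <- function(panel, model, metric = "rate_per_100k",
                              age_groups = "age_standardized", years = NULL,
                              outlier_k = 3) {
  by_sex <- compute_qci(panel, model, metric = metric,
                        sexes = c("female", "male"),
                        age_groups = age_groups, years = years) %>%
    select("location_id", "year", "sex", "age_group", "qci") %>%
    tidyr::pivot_wider(names_from = "sex", values_from = "qci",
                       names_prefix = "qci_")
  undefined <- filter(by_sex, !is.finite(.data$qci_male) | .data$qci_male <= 0)
  if (nrow(undefined) > 0) {
    warn(paste0(nrow(undefined),
                " stratum/strata with undefined GDR (male QCI = 0) dropped; see attr(., 'dropped')."))
  }
  out <- by_sex %>%
    filter(is.finite(.data$qci_male) & .data$qci_male > 0) %>%
    mutate(gdr = compute_gdr(.data$qci_female, .data$qci_male)) %>%
    group_by(.data$year, .data$age_group) %>%
    mutate(outlier = if (dplyr::n() >= 3) flag_outliers(.data$gdr, k = outlier_k)
           else rep(FALSE, dplyr::n())) %>%
    ungroup()
  attr(out, "dropped") <- undefined
  out
}

#' QCI by coarse age group
#'
#' Pools fine-band counts into childhood / adulthood / elderly per
#' (location, year, sex) - ratio-of-sums, the epidemiologically coherent
#' pooling - then computes the four ratios on the pooled counts and scores
#' them with the fixed reference model.
#'
#' @param panel A validated burden panel with fine-band `count` rows.
#' @param model The reference [fit_qci_model()].
#' @param scheme An [age_group_scheme()].
#' @param sexes,years Stratum selectors.
#' @return A `qci_tbl` keyed by (location_id, year, sex, age_group) with
#'   the coarse groups as `age_group`.
#' @export
qci_by_age_group <- function(panel, model, scheme = age_group_scheme(),
                             sexes = "both", years = NULL) {
  fine <- panel %>%
    filter(.data$metric == "count", .data$age_group %in% age_bands(),
           .data$sex %in% .env$sexes)
  if (!is.null(years)) fine <- filter(fine, .data$year %in% .env$years)
  if (nrow(fine) == 0) {
    abort("No fine-band count rows available for age-group pooling.",
          class = "qcindex_data_error")
  }
  pooled <- fine %>%
    mutate(group = assign_age_group(.data$age_group, scheme)) %>%
    group_by(.data$location_id, .data$year, .data$sex, .data$group, .data$measure) %>%
    summarise(value = sum(.data$value), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "measure", values_from = "value")
  missing_measures <- setdiff(epi_measures(), names(pooled))
  if (length(missing_measures) > 0) {
    abort(paste0("Measure(s) absent from fine-band counts: ",
                 paste(missing_measures, collapse = ", ")),
          class = "qcindex_data_error")
  }
  zero_denom <- pooled$incidence <= 0 | pooled$prevalence <= 0 | pooled$yld <= 0
  if (any(zero_denom)) {
    warn(paste0(sum(zero_denom), " pooled stratum/strata excluded for zero denominators."))
  }
  quartets <- pooled[!zero_denom, ] %>%
    mutate(
      mir = .data$deaths / .data$incidence,
      daly_to_prev = .data$daly / .data$prevalence,
      prev_to_inc = .data$prevalence / .data$incidence,
      yll_to_yld = .data$yll / .data$yld
    ) %>%
    select("location_id", "year", "sex", age_group = "group", all_of(ratio_names()))
  score_quartets(quartets, model)
}

#' Rank-based SDI quintile assignment
#'
#' Equal-count quintiles of the socio-demographic index across locations,
#' ordered `low < low-middle < middle < high-middle < high`. Ties are
#' broken by location identifier so the assignment is deterministic.
#'
#' @param sdi_by_location Tibble with columns `location_id, sdi` (>= 5
#'   locations).
#' @return The input with an ordered-factor `sdi_quintile` column.
#' @export
assign_sdi_quintiles <- function(sdi_by_location) {
  if (nrow(sdi_by_location) < 5) {
    abort("At least 5 locations are required for quintile assignment.",
          class = "qcindex_domain_error")
  }
  labels <- c("low", "low-middle", "middle", "high-middle", "high")
  sdi_by_location %>%
    arrange(.data$sdi, .data$location_id) %>%
    mutate(sdi_quintile = factor(
      labels[ceiling(row_number() * 5 / dplyr::n())],
      levels = labels, ordered = TRUE
    )) %>%
    arrange(.data$location_id)
}

#' Leave-one-out outlier flags
#'
#' `value_i` is flagged when it lies more than `k` standard deviations from
#' the mean of the *other* values: `|value_i - mean(v[-i])| > k *
#' sd(v[-i])`. Flagged values are retained - flags annotate, never remove.
#'
#' @param values Numeric vector, length >= 3.
#' @param k SD multiplier (default 3).
#' @return Logical vector of flags.
#' @export
flag_outliers <- function(values, k = 3) {
  n <- length(values)
  if (n < 3) {
    abort("At least 3 values are required for outlier detection.",
          class = "qcindex_domain_error")
  }
  if (any(!is.finite(values))) {
    abort("`values` must be finite.", class = "qcindex_domain_error")
  }
  vapply(seq_len(n), function(i) {
    rest <- values[-i]
    s <- sd(rest)
    if (s == 0) return(values[i] != rest[1])
    abs(values[i] - mean(rest)) > k * s
  }, logical(1))
}
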