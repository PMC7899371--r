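# Validity harness: country-random-intercept linear model for QCI and the
# headline Pearson correlation against an external reference index.

#' Pearson correlation with domain checks
#'
#' Sample Pearson coefficient of two equal-length (>= 3), non-constant
#' vectors. Invariant under positive affine transforms of either argument.
#'
#' @param a,b Numeric vectors.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_correlation <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3) {
    abort("`a` and `b` must have equal length >= 3.", class = "qcindex_domain_error")
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    abort("Inputs must be finite.", class = "qcindex_domain_error")
  }
  if (sd(a) == 0 || sd(b) == 0) {
    abort("Pearson correlation is undefined for a constant input.",
          class = "qcindex_undefined_correlation_error")
  }
  cor(a, b, method = "pearson")
}

#' Country-random-intercept linear model for QCI
#'
#' Fits `qci ~ covariates + (1 | location_id)` by restricted maximum
#' likelihood (REML, via lme4). Complete cases only; dropped rows are
#' reported in the result.
#'
#' @param data Tibble with columns `location_id`, `qci`, and the covariate
#'   columns.
#' @param covariates Character vector of fixed-effect covariate names
#'   (default: the four used for QCI validity - inpatient and outpatient
#'   utilization, deaths rate, prevalence rate).
#' @return Object of class `qci_validation`: fixed-effect estimates and
#'   standard errors, random-intercept and residual variances, counts of
#'   observations / groups / dropped rows, and the lme4 fit.
#' @export
fit_random_intercept_model <- function(data,
                                       covariates = c("inpatient_utilization",
                                                      "outpatient_utilization",
                                                      "deaths_rate",
                                                      "prevalence_rate")) {
  needed <- c("location_id", "qci", covariates)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "qcindex_data_error")
  }
  complete <- stats::complete.cases(data[, needed])
  n_dropped <- sum(!complete)
  fit_data <- data[complete, needed]
  if (length(unique(fit_data$location_id)) < 2) {
    abort("At least 2 groups (locations) are required.", class = "qcindex_data_error")
  }
  constant <- covariates[vapply(covariates, function(v) sd(fit_data[[v]]) == 0, logical(1))]
  if (length(constant) > 0) {
    abort(paste0("Constant covariate(s): ", paste(constant, collapse = ", ")),
          class = "qcindex_collinearity_error")
  }
  mm <- stats::model.matrix(
    stats::reformulate(covariates), data = fit_data)
  if (qr(mm)$rank < ncol(mm)) {
    abort(paste0("Collinear covariates; design matrix is rank-deficient among: ",
                 paste(covariates, collapse = ", ")),
          class = "qcindex_collinearity_error")
  }
  form <- stats::reformulate(c(covariates, "(1 | location_id)"), response = "qci")
  fit <- tryCatch(
    lme4::lmer(form, data = fit_data, REML = TRUE),
    error = function(e) abort(paste0("Mixed-model estimation failed: ",
                                     conditionMessage(e)),
                              class = "qcindex_estimation_error")
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  random_intercept_variance <- vc$vcov[vc$grp == "location_id"][1]
  residual_variance <- vc$vcov[vc$grp == "Residual"][1]
  coefs <- summary(fit)$coefficients
  fixed_effects <- tibble(
    term = rownames(coefs),
    estimate = coefs[, "Estimate"],
    std_error = coefs[, "Std. Error"]
  )
  structure(list(
    fixed_effects = fixed_effects,
    random_intercept_variance = random_intercept_variance,
    residual_variance = residual_variance,
    n_observations = nrow(fit_data),
    n_groups = length(unique(fit_data$location_id)),
    n_dropped = n_dropped,
    pearson_r_with_reference = NA_real_,
    fit = fit
  ), class = "qci_validation")
}

#' @export
print.qci_validation <- function(x, ...) {
  cat("QCI validity analysis\n")
  cat(sprintf("  n = %d observations, %d groups (%d incomplete rows dropped)\n",
              x$n_observations, x$n_groups, x$n_dropped))
  print(as.data.frame(x$fixed_effects), row.names = FALSE, digits = 4)
  cat(sprintf("  random-intercept variance: %.4f; residual variance: %.4f\n",
              x$random_intercept_variance, x$residual_variance))
  if (is.finite(x$pearson_r_with_reference)) {
    cat(sprintf("  Pearson r with reference index: %.3f\n",
                x$pearson_r_with_reference))
  }
  invisible(x)
}

#' Validate QCI against an external reference index
#'
#' Joins per-(location, year) QCI with a reference index and covariates,
#' fits the country-random-intercept model on the complete-case join, and
#' reports the simple Pearson correlation between QCI and the reference
#' index - the two validity outputs kept distinct.
#'
#' @param qci_table Tibble `location_id, year, qci`.
#' @param reference_table Tibble `location_id, year, reference_index`.
#' @param covariates Tibble `location_id, year` plus covariate columns used
#'   as fixed effects.
#' @return A `qci_validation` with `pearson_r_with_reference` filled in.
#' @export
validate_against_reference <- function(qci_table, reference_table, covariates) {
  joined <- qci_table %>%
    inner_join(reference_table, by = c("location_id", "year")) %>%
    inner_join(covariates, by = c("location_id", "year"))
  if (nrow(joined) == 0) {
    abort("Empty join: no shared (location, year) cells.", class = "qcindex_data_error")
  }
  covariate_cols <- setdiff(names(covariates), c("location_id", "year"))
  result <- fit_random_intercept_model(joined, covariates = covariate_cols)
  result$pearson_r_with_reference <-
    pearson_correlation(joined$qci, joined$reference_index)
  result
}
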