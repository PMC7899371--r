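# Index construction: secondary care-quality ratios -> z-standardization ->
# first principal component of the ratio correlation matrix -> orientation ->
# 0-100 min-max rescaling.

#' Secondary ratio names, in published coefficient order
#'
#' Order matters: (MIR, YLL-to-YLD, DALY-to-prevalence,
#' prevalence-to-incidence), matching the published composite-score
#' coefficients.
#'
#' @return Character vector of the four ratio column names.
#' @export
ratio_names <- function() c("mir", "yll_to_yld", "daly_to_prev", "prev_to_inc")

#' Published first-component loadings
#'
#' The fixed coefficients of the published composite score, in
#' [ratio_names()] order. Their squared norm is 1 to within 5e-6,
#' consistent with a unit-norm first eigenvector.
#'
#' @return Named numeric 4-vector.
#' @export
published_loadings <- function() {
  setNames(c(0.5003587, 0.5007964, 0.5002090, -0.4986332), ratio_names())
}

#' Compute the four secondary care-quality ratios per stratum
#'
#' For each selected stratum: `mir = deaths / incidence` (the
#' mortality-to-incidence ratio, a survival proxy), `daly_to_prev = DALY /
#' prevalence`, `prev_to_inc = prevalence / incidence`, and `yll_to_yld =
#' YLL / YLD`. Strata with a zero denominator are excluded with a warning
#' (never a silent NaN) and listed in the `excluded` attribute; a stratum
#' missing one of the six measures is an error.
#'
#' @param panel A validated burden panel.
#' @param metric `"rate_per_100k"` (default; ratios of age-standardized
#'   rates are the intended use) or `"count"`.
#' @param sexes,age_groups,years Stratum selectors (default: both sexes,
#'   age-standardized, all years present).
#' @return Tibble `location_id, year, sex, age_group, mir, daly_to_prev,
#'   prev_to_inc, yll_to_yld`, with attribute `excluded` (tibble of dropped
#'   strata and reasons).
#' @export
compute_secondary_ratios <- function(panel,
                                     metric = "rate_per_100k",
                                     sexes = "both",
                                     age_groups = "age_standardized",
                                     years = NULL) {
  metric <- match.arg(metric, epi_metrics())
  sub <- panel %>%
    filter(.data$metric == .env$metric, .data$sex %in% .env$sexes,
           .data$age_group %in% .env$age_groups)
  if (!is.null(years)) sub <- filter(sub, .data$year %in% .env$years)
  if (nrow(sub) == 0) {
    abort("No panel rows match the requested strata.", class = "qcindex_data_error")
  }
  wide <- sub %>%
    select("location_id", "year", "sex", "age_group", "measure", "value") %>%
    tidyr::pivot_wider(names_from = "measure", values_from = "value")
  missing_measures <- setdiff(epi_measures(), names(wide))
  if (length(missing_measures) > 0) {
    abort(paste0("Measure(s) absent from the selected strata: ",
                 paste(missing_measures, collapse = ", ")),
          class = "qcindex_data_error")
  }
  incomplete <- wide %>%
    filter(dplyr::if_any(all_of(epi_measures()), is.na))
  if (nrow(incomplete) > 0) {
    key <- paste(incomplete$location_id, incomplete$year, incomplete$sex,
                 incomplete$age_group, sep = "/")
    abort(c("Strata missing one or more of the six measures:",
            head(key, 10)), class = "qcindex_data_error")
  }
  zero_denom <- wide$incidence <= 0 | wide$prevalence <= 0 | wide$yld <= 0
  excluded <- wide[zero_denom, c("location_id", "year", "sex", "age_group")]
  if (nrow(excluded) > 0) {
    excluded$reason <- "zero denominator (incidence, prevalence or YLD)"
    warn(paste0(nrow(excluded),
                " stratum/strata excluded for zero denominators; see attr(., 'excluded')."))
  }
  out <- wide[!zero_denom, ] %>%
    mutate(
      mir = .data$deaths / .data$incidence,
      daly_to_prev = .data$daly / .data$prevalence,
      prev_to_inc = .data$prevalence / .data$incidence,
      yll_to_yld = .data$yll / .data$yld
    ) %>%
    select("location_id", "year", "sex", "age_group", all_of(ratio_names()))
  attr(out, "excluded") <- as_tibble(excluded)
  out
}

#' Standardize ratio quartets to z-scores
#'
#' Componentwise `zeta_j = (x_j - mu_j) / sigma_j`.
#'
#' @param quartets Tibble with the four [ratio_names()] columns.
#' @param mu,sigma Named numeric 4-vectors in [ratio_names()] order; all
#'   `sigma > 0`.
#' @return The input tibble with ratio columns replaced by their z-scores.
#' @export
standardize_ratios <- function(quartets, mu, sigma) {
  mu <- mu[ratio_names()]
  sigma <- sigma[ratio_names()]
  if (any(is.na(mu)) || any(is.na(sigma))) {
    abort("`mu` and `sigma` must be named by the four ratios.",
          class = "qcindex_domain_error")
  }
  degenerate <- ratio_names()[sigma <= 0]
  if (length(degenerate) > 0) {
    abort(paste0("Degenerate (zero or negative) standard deviation for ratio(s): ",
                 paste(degenerate, collapse = ", ")),
          class = "qcindex_degenerate_error")
  }
  out <- quartets
  for (r in ratio_names()) out[[r]] <- (quartets[[r]] - mu[[r]]) / sigma[[r]]
  out
}

ratio_matrix <- function(quartets) {
  as.matrix(quartets[, ratio_names()])
}

#' Fit a QCI scoring model on a reference set of ratio quartets
#'
#' Estimates per-ratio means and standard deviations from the reference
#' strata; takes the unit-norm first eigenvector of the 4x4 correlation
#' matrix of the ratios as loadings (unless fixed loadings are supplied,
#' e.g. [published_loadings()] for reproducibility of the published
#' formula); chooses the orientation sign so that a higher oriented score
#' means better care (negative association with the mortality-to-incidence
#' ratio); and records the min/max oriented score over the reference set as
#' the 0-100 rescaling bounds.
#'
#' @param quartets Reference tibble from [compute_secondary_ratios()]; at
#'   least 5 strata, each ratio with positive variance.
#' @param loadings Optional fixed 4-vector of loadings in [ratio_names()]
#'   order; `NULL` (default) fits them by eigendecomposition.
#' @param reference_set Free-text description stored in the model.
#' @return An object of class `qci_model`: list with `mu`, `sigma`,
#'   `loadings`, `orientation`, `score_min`, `score_max`, `reference_set`,
#'   `n_reference`.
#' @export
fit_qci_model <- function(quartets, loadings = NULL,
                          reference_set = "both-sex age-standardized country-years") {
  x <- ratio_matrix(quartets)
  if (nrow(x) < 5) {
    abort("At least 5 reference strata are required to fit the model.",
          class = "qcindex_domain_error")
  }
  if (any(!is.finite(x))) {
    abort("Reference ratios must be finite.", class = "qcindex_domain_error")
  }
  mu <- setNames(colMeans(x), ratio_names())
  sigma <- setNames(apply(x, 2, sd), ratio_names())
  degenerate <- ratio_names()[sigma <= 0]
  if (length(degenerate) > 0) {
    abort(paste0("Constant ratio column(s) in the reference set: ",
                 paste(degenerate, collapse = ", ")),
          class = "qcindex_degenerate_error")
  }
  z <- sweep(sweep(x, 2, mu), 2, sigma, "/")
  if (is.null(loadings)) {
    cc <- cor(x)
    eig <- eigen(cc, symmetric = TRUE)
    loadings <- eig$vectors[, 1]
    if (any(Im(as.complex(loadings)) != 0)) {
      abort("Eigendecomposition of the ratio correlation matrix failed.",
            class = "qcindex_numerical_error")
    }
  } else {
    if (length(loadings) != 4) {
      abort("`loadings` must have length 4.", class = "qcindex_domain_error")
    }
  }
  loadings <- setNames(as.numeric(loadings), ratio_names())
  scores_raw <- drop(z %*% loadings)
  r_mir <- suppressWarnings(cor(scores_raw, z[, "mir"]))
  orientation <- if (is.na(r_mir) || r_mir == 0) {
    if (loadings[["mir"]] > 0) -1 else 1
  } else if (r_mir > 0) -1 else 1
  scores <- orientation * scores_raw
  model <- structure(list(
    mu = mu, sigma = sigma, loadings = loadings,
    orientation = orientation,
    score_min = min(scores), score_max = max(scores),
    reference_set = reference_set, n_reference = nrow(x)
  ), class = "qci_model")
  if (model$score_min >= model$score_max) {
    abort("Degenerate score range on the reference set (all scores equal).",
          class = "qcindex_degenerate_error")
  }
  model
}

#' @export
print.qci_model <- function(x, ...) {
  cat("QCI scoring model\n")
  cat("  reference set:", x$reference_set, sprintf("(n = %d)\n", x$n_reference))
  cat("  loadings (oriented sign ", sprintf("%+d", x$orientation), "):\n", sep = "")
  print(round(x$loadings, 6))
  cat(sprintf("  score range: [%.4f, %.4f]\n", x$score_min, x$score_max))
  invisible(x)
}

#' Oriented principal-component score of ratio quartets
#'
#' `orientation * (loadings . zeta)` with `zeta` from [standardize_ratios()]
#' under the model's `mu` and `sigma`.
#'
#' @param model A fitted [fit_qci_model()].
#' @param quartets Tibble with the four ratio columns (raw, not
#'   standardized).
#' @return Numeric vector of oriented scores, one per row.
#' @export
pca_score <- function(model, quartets) {
  stopifnot(inherits(model, "qci_model"))
  zeta <- standardize_ratios(quartets, model$mu, model$sigma)
  model$orientation * drop(ratio_matrix(zeta) %*% model$loadings)
}

#' Published fixed-coefficient composite score
#'
#' Evaluates the published first-component formula at an already
#' standardized ratio vector: `0.5003587 zeta_MIR + 0.5007964
#' zeta_YLL-to-YLD + 0.5002090 zeta_DALY-to-prev - 0.4986332
#' zeta_prev-to-inc`. This is the reproducibility path that bypasses
#' [fit_qci_model()]; no orientation is applied.
#'
#' @param zeta Numeric 4-vector in [ratio_names()] order, or a matrix /
#'   tibble with those four columns (one score per row).
#' @return Numeric score(s).
#' @export
fixed_coefficient_score <- function(zeta) {
  coefs <- published_loadings()
  if (is.data.frame(zeta)) zeta <- as.matrix(zeta[, ratio_names()])
  if (is.matrix(zeta)) {
    if (ncol(zeta) != 4) abort("`zeta` must have 4 columns.", class = "qcindex_domain_error")
    return(drop(zeta %*% coefs))
  }
  if (length(zeta) != 4 || any(!is.finite(zeta))) {
    abort("`zeta` must be a finite numeric 4-vector.", class = "qcindex_domain_error")
  }
  sum(coefs * zeta)
}

#' Rescale oriented scores to the 0-100 QCI
#'
#' `100 * (score - score_min) / (score_max - score_min)`, clipped to
#' `[0, 100]` for strata scored outside the reference range. The reference
#' maximum maps to 100 (the best-performing reference stratum) and the
#' minimum to 0.
#'
#' @param model A fitted [fit_qci_model()].
#' @param score Oriented score(s) from [pca_score()].
#' @return QCI value(s) in `[0, 100]`.
#' @export
rescale_to_qci <- function(model, score) {
  stopifnot(inherits(model, "qci_model"))
  if (model$score_min >= model$score_max) {
    abort("Degenerate rescaling range: score_min >= score_max.",
          class = "qcindex_degenerate_error")
  }
  pmin(pmax(100 * (score - model$score_min) /
              (model$score_max - model$score_min), 0), 100)
}

#' Compute QCI for panel strata under a fitted model
#'
#' Composition of [compute_secondary_ratios()], [standardize_ratios()],
#' [pca_score()] and [rescale_to_qci()]. Strata excluded upstream (zero
#' denominators) propagate as explicit gaps via the `excluded` attribute.
#'
#' @inheritParams compute_secondary_ratios
#' @param model A fitted [fit_qci_model()].
#' @return Tibble of class `qci_tbl`: stratum keys, the four standardized
#'   ratios (`zeta_` prefix), `pca_score`, and `qci` in `[0, 100]`.
#' @export
compute_qci <- function(panel, model,
                        metric = "rate_per_100k",
                        sexes = "both",
                        age_groups = "age_standardized",
                        years = NULL) {
  quartets <- compute_secondary_ratios(panel, metric = metric, sexes = sexes,
                                       age_groups = age_groups, years = years)
  score_quartets(quartets, model)
}

#' @rdname compute_qci
#' @param quartets A ratio tibble from [compute_secondary_ratios()] (or
#'   pooled-count ratios), scored directly.
#' @export
score_quartets <- function(quartets, model) {
  stopifnot(inherits(model, "qci_model"))
  zeta <- standardize_ratios(quartets, model$mu, model$sigma)
  scores <- model$orientation * drop(ratio_matrix(zeta) %*% model$loadings)
  out <- quartets %>%
    select(-all_of(ratio_names())) %>%
    dplyr::bind_cols(setNames(as_tibble(ratio_matrix(zeta)),
                              paste0("zeta_", ratio_names()))) %>%
    mutate(pca_score = scores, qci = rescale_to_qci(model, scores))
  attr(out, "excluded") <- attr(quartets, "excluded")
  class(out) <- c("qci_tbl", class(out))
  out
}

# ---------------------------------------------------------------------------
# Model serialization

#' Serialize / restore a QCI model as YAML
#'
#' Round-trips every fitted quantity (means, standard deviations, loadings,
#' orientation, score bounds, reference description) at full double
#' precision so a model can be re-used exactly across runs.
#'
#' @param model A `qci_model`.
#' @param path File path.
#' @return `write_qci_model()`: `path`, invisibly. `read_qci_model()`: the
#'   restored `qci_model`.
#' @export
write_qci_model <- function(model, path) {
  stopifnot(inherits(model, "qci_model"))
  payload <- list(
    mu = as.list(model$mu), sigma = as.list(model$sigma),
    loadings = as.list(model$loadings),
    orientation = model$orientation,
    score_min = model$score_min, score_max = model$score_max,
    reference_set = model$reference_set, n_reference = model$n_reference
  )
  yaml::write_yaml(payload, path, precision = 17)
  invisible(path)
}

#' @rdname write_qci_model
#' @export
read_qci_model <- function(path) {
  payload <- yaml::read_yaml(path)
  structure(list(
    mu = unlist(payload$mu)[ratio_names()],
    sigma = unlist(payload$sigma)[ratio_names()],
    loadings = unlist(payload$loadings)[ratio_names()],
    orientation = payload$orientation,
    score_min = payload$score_min, score_max = payload$score_max,
    reference_set = payload$reference_set, n_reference = payload$n_reference
  ), class = "qci_model")
}
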