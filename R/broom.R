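# broom-style accessors for fitted objects.

#' Tidy a QCI scoring model
#'
#' One row per secondary ratio with its reference mean, standard deviation
#' and (unoriented) first-component loading.
#'
#' @param x A `qci_model`.
#' @param ... Unused.
#' @return Tibble `ratio, mean, sd, loading`.
#' @export
tidy.qci_model <- function(x, ...) {
  tibble(ratio = ratio_names(),
         mean = unname(x$mu[ratio_names()]),
         sd = unname(x$sigma[ratio_names()]),
         loading = unname(x$loadings[ratio_names()]))
}

#' @rdname tidy.qci_model
#' @return `glance()`: one-row tibble with orientation, score bounds and
#'   reference-set size.
#' @export
glance.qci_model <- function(x, ...) {
  tibble(orientation = x$orientation, score_min = x$score_min,
         score_max = x$score_max, n_reference = x$n_reference,
         reference_set = x$reference_set)
}

#' Tidy the QCI validity model
#'
#' @param x A `qci_validation`.
#' @param ... Unused.
#' @return `tidy()`: fixed-effect terms with estimates and standard errors.
#' @export
tidy.qci_validation <- function(x, ...) {
  x$fixed_effects
}

#' @rdname tidy.qci_validation
#' @return `glance()`: one-row tibble with variance components, the Pearson
#'   correlation with the reference index, and sample sizes.
#' @export
glance.qci_validation <- function(x, ...) {
  tibble(random_intercept_variance = x$random_intercept_variance,
         residual_variance = x$residual_variance,
         pearson_r_with_reference = x$pearson_r_with_reference,
         n_observations = x$n_observations, n_groups = x$n_groups,
         n_dropped = x$n_dropped)
}
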