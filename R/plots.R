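# ggplot2 displays for fitted models and result tables.

#' Plot the loadings of a QCI scoring model
#'
#' Bar chart of the oriented first-component loadings: bars pointing up
#' indicate ratios whose increase raises the index (better care).
#'
#' @param object A `qci_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qci_model
#' @export
autoplot.qci_model <- function(object, ...) {
  df <- tidy(object) %>%
    mutate(oriented = object$orientation * .data$loading)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio, y = .data$oriented)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "oriented loading",
                  title = "QCI first-component loadings (oriented)") +
    ggplot2::theme_minimal()
}

#' Plot a QCI result table
#'
#' QCI trajectories over years, one line per location (thinned to at most
#' `max_locations` for legibility), with the cross-location mean overlaid.
#'
#' @param object A `qci_tbl` from [compute_qci()].
#' @param max_locations Maximum number of location lines drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qci_tbl
#' @export
autoplot.qci_tbl <- function(object, max_locations = 30, ...) {
  locs <- unique(object$location_id)
  keep <- locs[unique(round(seq(1, length(locs), length.out = min(max_locations, length(locs)))))]
  mean_line <- object %>% group_by(.data$year) %>%
    summarise(qci = mean(.data$qci), .groups = "drop")
  ggplot2::ggplot(filter(object, .data$location_id %in% keep),
                  ggplot2::aes(x = .data$year, y = .data$qci,
                               group = .data$location_id)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::geom_line(data = mean_line, ggplot2::aes(group = NULL),
                       colour = "firebrick", linewidth = 1) +
    ggplot2::labs(y = "QCI (0-100)", title = "Quality of Care Index by location-year") +
    ggplot2::theme_minimal()
}

#' QCI distribution by SDI quintile
#'
#' @param qci_table Tibble with `qci` and `sdi_quintile` columns.
#' @return A ggplot boxplot.
#' @export
plot_qci_by_sdi <- function(qci_table) {
  ggplot2::ggplot(qci_table,
                  ggplot2::aes(x = .data$sdi_quintile, y = .data$qci)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = "SDI quintile", y = "QCI (0-100)",
                  title = "Care quality by socio-demographic quintile") +
    ggplot2::theme_minimal()
}

#' Gender disparity ratio distribution
#'
#' Histogram of female-to-male QCI ratios with the parity line at 1;
#' flagged outliers drawn as rug marks.
#'
#' @param gdr_table Output of [compute_gdr_table()].
#' @return A ggplot object.
#' @export
plot_gdr <- function(gdr_table) {
  ggplot2::ggplot(gdr_table, ggplot2::aes(x = .data$gdr)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = 1, colour = "firebrick", linetype = 2) +
    ggplot2::geom_rug(data = filter(gdr_table, .data$outlier), colour = "firebrick") +
    ggplot2::labs(x = "GDR (female / male QCI)", y = "strata",
                  title = "Gender disparity in care quality") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
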