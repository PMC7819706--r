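#' Phylostratigraphy scatter/box plot of a property against age
#'
#' One box per age class (width proportional to the number of datapoints,
#' whiskers at the 9% and 91% quantiles, outliers hidden) with the ordinary
#' least-squares trend line over all datapoints overlaid.
#'
#' @param datapoints Datapoint tibble with `age_my`, `age_class` and the
#'   property column.
#' @param property Property column name (string).
#' @return A ggplot object.
#' @export
plot_phylostrat <- function(datapoints, property) {
  d <- datapoints[!is.na(datapoints[[property]]), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age_my / 1000,
                                  y = .data[[property]])) +
    ggplot2::geom_boxplot(ggplot2::aes(group = .data$age_class),
                          varwidth = TRUE, outlier.shape = NA,
                          colour = "grey55", fill = "grey90") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "steelblue") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Age (BY)", y = property) +
    ggplot2::theme_minimal()
}

#' Plot a per-amino-acid slope profile
#'
#' @param object An `aa_slope_profile` from [aa_slope_profile()].
#' @param ... Unused.
#' @return A ggplot object: slope with standard-error bars per amino acid.
#' @export
autoplot.aa_slope_profile <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$aa, y = .data$slope)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$slope - .data$se,
                                          ymax = .data$slope + .data$se)) +
    ggplot2::labs(x = NULL, y = "Slope (percentage points per BY)",
                  title = unique(d$subset)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a minimum-age sweep of profile correlations
#'
#' @param sweep Output of [min_age_sweep()].
#' @return A ggplot object: correlation against minimum age with
#'   Fisher-transform error bounds where available.
#' @export
plot_min_age_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$min_age_my / 1000,
                                      y = .data$rho)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$rho_low,
                                          ymax = .data$rho_high)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Minimum age included (BY)",
                  y = "Correlation with property") +
    ggplot2::theme_minimal()
}
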