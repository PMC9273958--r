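#' Plot a population simulation
#'
#' Biomass density, post-egg abundance and mean age over time; the spin-up
#' period is shaded.
#'
#' @param object a `debibm_sim`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot debibm_sim
#' @export
autoplot.debibm_sim <- function(object, ...) {
  long <- as_tibble(object) |>
    select("t_days", "biomass_kg_km2", "total_abundance", "mean_age_y",
           "spinup") |>
    tidyr::pivot_longer(-c("t_days", "spinup"),
                        names_to = "quantity", values_to = "value")
  spin_end <- attr(object, "spinup_years") * 365
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_days / 365, y = .data$value)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = spin_end / 365,
                      ymin = -Inf, ymax = Inf, alpha = 0.12) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (years)", y = NULL,
                  title = sprintf("Population run '%s'", attr(object, "label")))
}

#' Plot a forcing series
#'
#' @param object a `debibm_forcing`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot debibm_forcing
#' @export
autoplot.debibm_forcing <- function(object, ...) {
  long <- object$steps |>
    select("t_days", "temperature_C", "food_index", "Z_F") |>
    tidyr::pivot_longer(-"t_days", names_to = "variable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_days / 365, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (years)", y = NULL,
                  title = sprintf("Forcings '%s'", object$label))
}

#' Plot a trait report
#'
#' Observed versus predicted zero-variate traits on log-log axes.
#'
#' @param object a `debibm_traits` report (with an `observed` column).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot debibm_traits
#' @export
autoplot.debibm_traits <- function(object, ...) {
  stopifnot("observed" %in% names(object))
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$observed, y = .data$predicted,
                               label = .data$trait)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "observed", y = "predicted",
                  title = "Zero-variate traits: observed vs predicted")
}
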