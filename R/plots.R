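#' Plot site synchrony against its candidate drivers
#'
#' Scatterplots of community synchrony phi against temperature variability,
#' mean temporal turnover, and discharge variability, one panel each.
#'
#' @param object A `site_summary` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot site_summary
#' @export
autoplot.site_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("temp_sd", "turnover_mean", "discharge_sd"),
                              names_to = "driver", values_to = "value")
  long$driver <- factor(long$driver,
                        levels = c("temp_sd", "turnover_mean", "discharge_sd"),
                        labels = c("Temperature SD (°C)",
                                   "Mean turnover",
                                   "Discharge SD (m³/s)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$phi)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$p_value < 0.05), size = 2) +
    ggplot2::facet_wrap(~driver, scales = "free_x") +
    ggplot2::labs(x = NULL, y = expression(phi),
                  colour = "Synchrony\nsignificant") +
    ggplot2::theme_minimal()
}

#' Plot per-taxon contribution z-scores
#'
#' Jittered z-scores, grouped by functional feeding group when a `group`
#' column is present (otherwise by site), with the classification thresholds
#' at +/- `z_crit` marked.
#'
#' @param object A `taxon_contributions` tibble.
#' @param z_crit Threshold lines (default 1.96).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot taxon_contributions
#' @export
autoplot.taxon_contributions <- function(object, z_crit = 1.96, ...) {
  df <- tibble::as_tibble(object)
  xvar <- if ("group" %in% names(df)) "group" else "site"
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[xvar]], y = .data$z)) +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$classification),
                         width = 0.25, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = c(-z_crit, z_crit), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(
      positive = "#2166ac", negative = "#b2182b",
      nonsignificant = "grey60", degenerate = "black")) +
    ggplot2::labs(x = NULL, y = "contribution z-score") +
    ggplot2::theme_minimal()
}

#' Plot per-interval temporal turnover
#'
#' @param object A `turnover_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot turnover_result
#' @export
autoplot.turnover_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year_to, y = .data$turnover)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = attr(object, "mean_turnover"),
                        linetype = "dotted") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "year", y = "turnover (gains + losses / union richness)") +
    ggplot2::theme_minimal()
}
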