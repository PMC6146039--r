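#' Plot green-area growth trajectories
#'
#' One line per plant, coloured by condition (when present), log-scale
#' area axis so exponential growth is linear.
#'
#' @param series Tibble from [build_timeseries()].
#' @return A ggplot.
#' @export
plot_growth_curves <- function(series) {
  has_cond <- "condition" %in% names(series)
  p <- ggplot2::ggplot(series, ggplot2::aes(
    x = .data$timestamp_h, y = .data$green_area_px,
    group = .data$well,
    colour = if (has_cond) .data$condition else NULL)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (h)", y = "green area (px)",
                  colour = if (has_cond) "condition" else NULL) +
    ggplot2::theme_minimal()
  p
}

#' Parallel-coordinate plot of per-trait log2 changes
#'
#' The standard view of the PBC decomposition: one axis per trait, one
#' line per variant, facetted by growth condition (the control condition
#' carries four traits, the stress conditions three).
#'
#' @param pbc A [compute_pbc()] table.
#' @return A ggplot.
#' @export
plot_parallel_coords <- function(pbc) {
  long <- pbc |>
    pivot_longer(dplyr::starts_with("log2_"), names_to = "trait",
                 values_to = "log2_change", names_prefix = "log2_") |>
    filter(!is.na(.data$log2_change)) |>
    mutate(trait = factor(.data$trait, levels = c("germination", "establishment",
                                                  "growth", "color")))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$trait, y = .data$log2_change,
    group = interaction(.data$compound, .data$conc_mM),
    colour = .data$compound)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = NULL, y = "log2(variant / control)") +
    ggplot2::theme_minimal()
}

#' Radar chart of PBC index by concentration
#'
#' Concentrations as the radial axes, PBC index as the value, one polygon
#' per compound, facetted by condition.
#'
#' @param pbc A [compute_pbc()] table.
#' @return A ggplot.
#' @export
plot_radar <- function(pbc) {
  df <- pbc |>
    mutate(conc = factor(.data$conc_mM, levels = sort(unique(.data$conc_mM))))
  closed <- bind_rows(df, df |> filter(.data$conc == levels(df$conc)[1]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$conc, y = .data$pbc,
                                   group = .data$compound,
                                   colour = .data$compound)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_polygon(data = closed, ggplot2::aes(fill = .data$compound),
                          alpha = 0.1) +
    ggplot2::geom_point() +
    ggplot2::coord_polar() +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "concentration (mM)", y = "PBC index") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.germination_calibration <- function(object, ...) {
  df <- object$fit$model
  ggplot2::ggplot(df, ggplot2::aes(x = .data$abs_per_seed,
                                   y = .data$germination_pct)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::labs(x = "absorbance per seed (OD)", y = "germination (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
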