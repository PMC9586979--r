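# ggplot2 autoplot methods for result objects.

#' Plot a WUE-salinity fit
#'
#' Scatter of the underlying records with the fitted line.
#'
#' @param object A `wue_salinity_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot wue_salinity_fit
#' @export
autoplot.wue_salinity_fit <- function(object, ...) {
  df <- object$model$model
  names(df) <- c("wue", "salinity")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$salinity, y = .data$wue)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
      colour = "firebrick") +
    ggplot2::labs(
      x = "Porewater salinity (psu)",
      y = expression(WUE[int] ~ (mu * mol ~ CO[2] ~ mol ~ H[2] * O^-1)),
      title = sprintf("Intrinsic WUE vs salinity (slope %.2f, r² %.2f)",
        object$slope, object$r_squared))
}

#' Plot a water account
#'
#' Per-ecoregion water-use reductions for the average and potential
#' scenarios.
#'
#' @param object A `water_account` from [build_account()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot water_account
#' @export
autoplot.water_account <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object),
    cols = c("reduction_avg_mm", "reduction_pot_mm"),
    names_to = "scenario", values_to = "reduction_mm")
  df$scenario <- ifelse(df$scenario == "reduction_avg_mm", "average",
    "potential")
  ggplot2::ggplot(df, ggplot2::aes(
      x = stats::reorder(.data$name, .data$reduction_mm),
      y = .data$reduction_mm, fill = .data$scenario)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL,
      y = expression(Reduction ~ by ~ mangrove ~ water ~ use ~
          (mm ~ H[2] * O ~ yr^-1)),
      fill = "Scenario")
}

#' Plot a growth trajectory
#'
#' Geometry and water use of one simulated tree over time.
#'
#' @param object A `bettina_trajectory` from [bettina_simulate()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bettina_trajectory
#' @export
autoplot.bettina_trajectory <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object),
    cols = c("h_stem", "dbh_cm", "r_crown", "r_root", "uptake_l_day"),
    names_to = "measure", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "Age (yr)", y = NULL,
      title = sprintf("Tree growth at %.0f psu",
        attr(object, "config")$salinity))
}

#' Plot a salinity sweep
#'
#' Final tree water use against porewater salinity, with the
#' actual-to-potential transpiration ratio.
#'
#' @param object A `salinity_sweep` from [salinity_sweep()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot salinity_sweep
#' @export
autoplot.salinity_sweep <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
    ggplot2::aes(x = .data$salinity_psu, y = .data$uptake_l_day)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$uptake_ratio), alpha = 0.7) +
    ggplot2::labs(x = "Porewater salinity (psu)",
      y = expression(Tree ~ water ~ use ~ (L ~ day^-1)),
      size = "actual / potential")
}
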