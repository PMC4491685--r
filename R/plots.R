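#' Plot H/D depth profiles for a beamline configuration
#'
#' Depth profiles of the modeled H/D along lines parallel to the beam axis,
#' one panel per off-axis distance, one curve per proton energy.
#'
#' @param config An in-water [beamline_config()].
#' @param energies Proton beam energies (MeV).
#' @param offsets_cm Off-axis line distances (cm).
#' @param depths_cm Depths at which to evaluate (cm).
#' @return A ggplot object.
#' @export
plot_depth_profiles <- function(config, energies = c(100, 150, 200, 250),
                                offsets_cm = c(0, 10, 40, 80),
                                depths_cm = seq(2, 40, by = 1)) {
  stop_unless(inherits(config, "beamline_config") &&
                config$geometry$environment == "in_water",
              "`config` must be an in-water beamline_config")
  z_surface <- config$geometry$d_iso - config$geometry$iso_depth
  pts <- tidyr::expand_grid(x_cm = offsets_cm, depth_cm = depths_cm) |>
    dplyr::mutate(y_cm = 0, z_cm = z_surface + .data$depth_cm)
  df <- purrr::map(energies, function(E) {
    evaluate_hd(pts, config, energy = E)
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth_cm, y = .data$hd_Sv_per_Gy,
                                   colour = factor(.data$energy_MeV))) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~x_cm, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Depth in phantom (cm)", y = "H/D (Sv/Gy)",
                  colour = "E (MeV)",
                  title = paste0("Leakage-neutron H/D depth profiles: ",
                                 config$name))
}

#' Plot the regime apportionment fractions versus proton energy
#'
#' @param app A [regime_apportionment()].
#' @param energies Energies at which to evaluate (MeV).
#' @param renormalize Plot renormalized (default) or raw fractions.
#' @return A ggplot object.
#' @export
plot_regime_fractions <- function(app, energies = seq(100, 250, by = 2),
                                  renormalize = TRUE) {
  df <- regime_fractions(energies, app, renormalize = renormalize) |>
    tidyr::pivot_longer(-"energy_MeV", names_to = "regime", values_to = "fraction")
  df$regime <- factor(df$regime, levels = regime_names())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$energy_MeV, y = .data$fraction,
                                   colour = .data$regime)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Proton beam energy (MeV)", y = "Fraction of H/D",
                  colour = "Neutron regime")
}

#' Observed-versus-modeled plot for a fitted H/D model
#'
#' Log-log scatter of modeled against observed H/D, coloured by proton
#' energy, with the identity line.
#'
#' @param object An `hd_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hd_fit <- function(object, ...) {
  df <- object$residuals
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hd_Sv_per_Gy,
                                   y = .data$hd_model_Sv_per_Gy,
                                   colour = factor(.data$energy_MeV))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Observed H/D (Sv/Gy)", y = "Modeled H/D (Sv/Gy)",
                  colour = "E (MeV)",
                  title = sprintf("Fit of %s: mean |rel. err.| %.2g%%",
                                  object$config$name, object$error_stats$mean_pct))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
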