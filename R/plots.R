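# ggplot2 views of the result tables. Each plot function takes the tibble
# its module emits and returns a ggplot object.

#' Plot a photovoltaic table
#'
#' Electron-injection free energy per dye, coloured by light-harvesting
#' efficiency; lower bars mean more spontaneous injection.
#'
#' @param data A [photovoltaic_table()] result (needs `id`, `dg_inject`,
#'   `lhe`).
#' @return A ggplot.
#' @examples
#' plot_photovoltaics(benzil_table("photovoltaics"))
#' @export
plot_photovoltaics <- function(data) {
  check_columns(data, c("id", "dg_inject", "lhe"))
  ggplot2::ggplot(data, ggplot2::aes(x = stats::reorder(.data$id, .data$dg_inject),
                                     y = .data$dg_inject, fill = .data$lhe)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = expression(Delta * G[inject] ~ "(eV)"),
                  fill = "LHE") +
    ggplot2::theme_minimal()
}

#' Plot a torsion profile
#'
#' @param profile A profile tibble (`angle_deg`, `energy`), optionally with
#'   an `id` column for facetting several molecules.
#' @return A ggplot.
#' @examples
#' plot_torsion_profile(generate_torsion_profile(16.3175, 2, 130, 10))
#' @export
plot_torsion_profile <- function(profile) {
  check_columns(profile, c("angle_deg", "energy"), arg = "profile")
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$angle_deg, y = .data$energy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Dihedral angle (°)", y = "Relative energy (kJ/mol)") +
    ggplot2::theme_minimal()
  if ("id" %in% names(profile)) p <- p + ggplot2::facet_wrap(~id)
  p
}

#' Plot calculated-vs-observed band agreement
#'
#' Scatter of observed against calculated wavenumbers with the identity
#' line; tight clustering around the line is what a good scaling factor
#' buys.
#'
#' @param pairs A pair tibble from [pair_bands()] or [vibrational_pairs()].
#' @return A ggplot.
#' @examples
#' plot_band_agreement(vibrational_pairs(benzil_vibrations("BZL"), "IR"))
#' @export
plot_band_agreement <- function(pairs) {
  check_columns(pairs, c("calc", "obs"), arg = "pairs")
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$calc, y = .data$obs)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression("Calculated (cm"^-1 * ")"),
                  y = expression("Observed (cm"^-1 * ")")) +
    ggplot2::theme_minimal()
}

#' @describeIn qsar_fit Observed-vs-fitted plot; for an exact (square)
#'   solve all points sit on the identity line.
#' @param object A `qsar_fit`.
#' @export
autoplot.qsar_fit <- function(object, ...) {
  data <- tibble(
    id = if (is.null(object$design_ids)) as.character(seq_along(object$y)) else object$design_ids,
    observed = object$y,
    fitted = object$fitted
  )
  ggplot2::ggplot(data, ggplot2::aes(x = .data$observed, y = .data$fitted,
                                     label = .data$id)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Observed binding energy", y = "Fitted binding energy") +
    ggplot2::theme_minimal()
}
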