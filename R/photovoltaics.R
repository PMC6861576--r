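#' Light-harvesting efficiency from oscillator strength
#'
#' The fraction of incident light a sensitizer absorbs at its absorption
#' maximum, \eqn{LHE = 1 - 10^{-f}}, a standard figure of merit for
#' dye-sensitised solar-cell (DSSC) candidates. Strictly increasing in `f`,
#' bounded in \[0, 1).
#'
#' @param f Oscillator strength(s), dimensionless, `>= 0`.
#' @return LHE fraction(s) in \[0, 1).
#' @examples
#' light_harvesting_efficiency(c(0.608, 1.036))
#' @export
light_harvesting_efficiency <- function(f) {
  f <- as.numeric(f)
  if (any(!is.finite(f)) || any(f < 0)) {
    abort("Oscillator strength `f` must be finite and >= 0.",
          class = "benzilkit_error_domain")
  }
  1 - 10^(-f)
}

#' Vertical excitation energy from an absorption maximum
#'
#' Converts an absorption-maximum wavelength to the vertical excitation
#' energy E(0,0) as `constant / lambda_nm`. The default conversion constant
#' is the conventional 1240 eV nm; the exact value hc = 1239.84193 eV nm can
#' be passed instead when a table was built with it.
#'
#' @param lambda_nm Wavelength(s) at the absorption maximum, nm, `> 0`.
#' @param constant eV nm conversion constant (default 1240).
#' @return Excitation energy(ies), eV.
#' @examples
#' vertical_excitation_energy(276.39)
#' @export
vertical_excitation_energy <- function(lambda_nm, constant = 1240) {
  lambda_nm <- as.numeric(lambda_nm)
  if (any(!is.finite(lambda_nm)) || any(lambda_nm <= 0)) {
    abort("`lambda_nm` must be finite and > 0.", class = "benzilkit_error_domain")
  }
  constant / lambda_nm
}

#' Excited-state oxidation energy and electron-injection free energy
#'
#' From the ground-state oxidation energy of the dye (taken as -E(HOMO)),
#' the vertical excitation energy and the semiconductor conduction-band
#' energy: \eqn{E^*_{dye} = E_{dye} - E(0,0)} and
#' \eqn{\Delta G_{inject} = E^*_{dye} + E_{CB}}. With the sign convention
#' used here E_CB is negative (TiO2: -4.00 eV), so a more negative
#' \eqn{\Delta G_{inject}} means more spontaneous electron injection.
#'
#' @param e_dye Ground-state oxidation energy(ies), eV.
#' @param e00 Vertical excitation energy(ies), eV, `> 0`.
#' @param e_cb Conduction-band energy, eV (default -4.00, TiO2).
#' @return A tibble with columns `e_dye_star` and `dg_inject` (eV).
#' @examples
#' injection_free_energy(6.596043, vertical_excitation_energy(276.39))
#' @export
injection_free_energy <- function(e_dye, e00, e_cb = -4.00) {
  e_dye <- as.numeric(e_dye)
  e00 <- as.numeric(e00)
  if (any(!is.finite(e00)) || any(e00 <= 0)) {
    abort("`e00` must be finite and > 0.", class = "benzilkit_error_domain")
  }
  e_dye_star <- e_dye - e00
  tibble(e_dye_star = e_dye_star, dg_inject = e_dye_star + e_cb)
}

#' Photovoltaic modelling table for a dye series
#'
#' Runs the full DSSC sensitizer chain for each row: light-harvesting
#' efficiency from `f`, vertical excitation energy from `lambda_max_nm`,
#' frontier-orbital gap, ground- and excited-state oxidation energies and
#' the electron-injection free energy against the conduction band.
#'
#' @param data A data frame with columns `id`, `f`, `lambda_max_nm`,
#'   `e_homo`, `e_lumo`.
#' @param e_cb Semiconductor conduction-band energy, eV (default -4.00,
#'   TiO2).
#' @param constant eV nm conversion constant for
#'   [vertical_excitation_energy()].
#' @return A tibble with columns `id`, `f`, `lhe`, `lambda_max_nm`, `e00`,
#'   `e_homo`, `e_lumo`, `gap_ev`, `e_dye`, `e_dye_star`, `e_cb`,
#'   `dg_inject`.
#' @examples
#' benzil_molecules() |>
#'   dplyr::mutate(f = purrr::map_dbl(excitations, ~ .x$f[1]),
#'                 lambda_max_nm = purrr::map_dbl(excitations, ~ .x$lambda_nm[1])) |>
#'   photovoltaic_table()
#' @export
photovoltaic_table <- function(data, e_cb = -4.00, constant = 1240) {
  check_columns(data, c("id", "f", "lambda_max_nm", "e_homo", "e_lumo"))
  e00 <- vertical_excitation_energy(data$lambda_max_nm, constant)
  e_dye <- -data$e_homo
  inj <- injection_free_energy(e_dye, e00, e_cb)
  tibble(
    id = data$id,
    f = data$f,
    lhe = light_harvesting_efficiency(data$f),
    lambda_max_nm = data$lambda_max_nm,
    e00 = e00,
    e_homo = data$e_homo,
    e_lumo = data$e_lumo,
    gap_ev = orbital_gap(data$e_homo, data$e_lumo),
    e_dye = e_dye,
    e_dye_star = inj$e_dye_star,
    e_cb = e_cb,
    dg_inject = inj$dg_inject
  )
}

#' Select the best sensitizer from a photovoltaic table
#'
#' The dye with the most negative electron-injection free energy; ties are
#' broken by higher light-harvesting efficiency, then id order.
#'
#' @param data A photovoltaic table (needs `id`, `dg_inject`, `lhe`).
#' @return The winning id (length-1 character).
#' @examples
#' benzil_table("photovoltaics") |> select_best_sensitizer()
#' @export
select_best_sensitizer <- function(data) {
  check_columns(data, c("id", "dg_inject", "lhe"))
  if (nrow(data) == 0) {
    abort("Need at least one record.", class = "benzilkit_error_input")
  }
  ord <- order(data$dg_inject, -data$lhe, data$id)
  data$id[ord[1]]
}
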