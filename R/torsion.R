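# Torsional potential-energy-profile analysis. A profile is a tibble with
# columns angle_deg (strictly increasing grid in [0, 360)) and energy.

hartree_kj_mol <- 2625.50

check_profile <- function(profile, arg = "profile") {
  check_columns(profile, c("angle_deg", "energy"), arg = arg)
  if (nrow(profile) == 0) {
    abort("Torsion profile is empty.", class = "benzilkit_error_input")
  }
  if (any(!is.finite(profile$energy))) {
    abort("Torsion-scan energies must be finite.", class = "benzilkit_error_validation")
  }
  if (any(profile$angle_deg < 0 | profile$angle_deg >= 360) ||
      any(diff(profile$angle_deg) <= 0)) {
    abort("Angles must be a strictly increasing grid in [0, 360).",
          class = "benzilkit_error_validation")
  }
  invisible(profile)
}

#' Convert a torsion profile to relative energies
#'
#' Shifts the profile so its minimum is zero; hartree inputs are first
#' converted to kJ/mol (2625.50 kJ/mol per hartree).
#'
#' @param profile Tibble with `angle_deg` and `energy` columns.
#' @param unit_in `"kj_mol"` or `"hartree"`.
#' @return The profile with `energy` relative in kJ/mol (minimum 0).
#' @examples
#' torsion_relative(tibble::tibble(angle_deg = c(0, 90), energy = c(0, 0.01)),
#'                  unit_in = "hartree")
#' @export
torsion_relative <- function(profile, unit_in = c("kj_mol", "hartree")) {
  unit_in <- match.arg(unit_in)
  check_profile(profile)
  e <- profile$energy
  if (unit_in == "hartree") e <- e * hartree_kj_mol
  profile$energy <- e - min(e)
  as_tibble(profile)
}

#' Grid-level extrema of a torsion profile
#'
#' The global minimum and maximum of the scanned profile, reported at grid
#' resolution (no interpolation); ties are broken by the smallest angle.
#' A flat profile returns equal min and max with a warning and a
#' `flat = TRUE` column.
#'
#' @param profile Tibble with `angle_deg` and `energy` columns.
#' @return A tibble with rows `min` and `max`: columns `extremum`,
#'   `angle_deg`, `energy`, `flat`.
#' @examples
#' torsion_extrema(generate_torsion_profile(16.3175, 2, 130, 10))
#' @export
torsion_extrema <- function(profile) {
  check_profile(profile)
  flat <- diff(range(profile$energy)) == 0
  if (flat) {
    warn("Flat torsion profile: minimum and maximum coincide.")
  }
  i_min <- which.min(profile$energy)  # which.min/max take the first = smallest angle
  i_max <- which.max(profile$energy)
  tibble(
    extremum = c("min", "max"),
    angle_deg = profile$angle_deg[c(i_min, i_max)],
    energy = profile$energy[c(i_min, i_max)],
    flat = flat
  )
}

#' Conformational barrier height of a torsion profile
#'
#' Energy difference between the global maximum and global minimum of the
#' scan. Invariant under adding any constant to all energies.
#'
#' @param profile Tibble with `angle_deg` and `energy` columns.
#' @return Barrier height, kJ/mol, `>= 0`.
#' @examples
#' barrier_height(generate_torsion_profile(16.3175, 2, 130, 10))
#' @export
barrier_height <- function(profile) {
  check_profile(profile)
  max(profile$energy) - min(profile$energy)
}

#' Order molecules by conformational barrier
#'
#' @param data Long tibble of profiles with columns `id`, `angle_deg`,
#'   `energy`.
#' @return A tibble with `id` and `barrier_kj_mol`, sorted descending by
#'   barrier; ties broken by id.
#' @examples
#' meta <- benzil_table("torsion_metadata")
#' profs <- purrr::map2_dfr(meta$id, meta$barrier_kj_mol, function(id, a) {
#'   dplyr::mutate(generate_torsion_profile(a, 2, 130, 10), id = id)
#' })
#' order_barriers(profs)
#' @export
order_barriers <- function(data) {
  check_columns(data, c("id", "angle_deg", "energy"))
  if (nrow(data) == 0) {
    abort("Need at least one profile.", class = "benzilkit_error_input")
  }
  data %>%
    group_by(.data$id) %>%
    summarise(barrier_kj_mol = barrier_height(
      data.frame(angle_deg = .data$angle_deg, energy = .data$energy)
    ), .groups = "drop") %>%
    arrange(desc(.data$barrier_kj_mol), .data$id)
}

#' Read a torsion profile CSV
#'
#' Expects `angle_deg,energy` rows after a `# unit: kJ/mol` (or
#' `# unit: hartree`) comment line; the result is converted to relative
#' kJ/mol via [torsion_relative()].
#'
#' @param path CSV path.
#' @return A relative profile tibble.
#' @export
read_torsion_profile <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File '%s' does not exist.", path), class = "benzilkit_error_io")
  }
  first <- readLines(path, n = 1)
  unit <- if (grepl("hartree", first, ignore.case = TRUE)) "hartree" else "kj_mol"
  profile <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  torsion_relative(profile, unit_in = unit)
}
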