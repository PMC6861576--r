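#' Conceptual-DFT global reactivity descriptors
#'
#' Computes the standard global reactivity descriptors from a vertical
#' ionisation potential and electron affinity (both eV):
#' electronegativity \eqn{\chi = (IP + EA)/2}, chemical potential
#' \eqn{\mu = -\chi}, hardness \eqn{\eta = (IP - EA)/2}, softness
#' \eqn{S = 1/\eta}, electrophilicity index \eqn{\omega = \mu^2/(2\eta)},
#' and the IP-EA gap \eqn{IP - EA = 2\eta}.
#'
#' All arithmetic is full double precision; rounding belongs to the
#' presentation layer (see [reactivity_descriptors()] with
#' `style = "printed"` for reproducing published 3-decimal tables).
#'
#' @param ip Vertical ionisation potential(s), eV.
#' @param ea Vertical electron affinity(ies), eV. Must satisfy `ip > ea`
#'   elementwise, otherwise the hardness would be nonpositive.
#' @return A tibble with columns `ip`, `ea`, `chi`, `mu_chem`, `eta`, `s`,
#'   `omega`, `gap_ipea`.
#' @examples
#' compute_descriptors(8.748, 6.065)
#' @export
compute_descriptors <- function(ip, ea) {
  ip <- as.numeric(ip)
  ea <- as.numeric(ea)
  if (length(ip) != length(ea)) {
    abort("`ip` and `ea` must have the same length.", class = "benzilkit_error_input")
  }
  if (any(!is.finite(ip)) || any(!is.finite(ea))) {
    abort("`ip` and `ea` must be finite.", class = "benzilkit_error_input")
  }
  if (any(ip <= ea)) {
    abort(
      "`ip` must exceed `ea` for every record (hardness would be nonpositive).",
      class = "benzilkit_error_hardness"
    )
  }
  chi <- (ip + ea) / 2
  eta <- (ip - ea) / 2
  mu <- -chi
  tibble(
    ip = ip, ea = ea,
    chi = chi, mu_chem = mu, eta = eta,
    s = 1 / eta, omega = mu^2 / (2 * eta),
    gap_ipea = ip - ea
  )
}

#' Reactivity-descriptor table for a molecule series
#'
#' Data-frame-first wrapper around [compute_descriptors()]: takes a tibble
#' with `ip` and `ea` columns (eV), keeps any identifier columns, and
#' appends the descriptor columns.
#'
#' `style = "printed"` reproduces how 3-decimal published tables are built:
#' \eqn{\chi}, \eqn{\mu} and \eqn{\eta} are rounded to 3 decimals first and
#' \eqn{S} and \eqn{\omega} are then computed *from the rounded values*.
#' Published descriptor tables commonly propagate display rounding this way,
#' and their S/omega columns cannot be reproduced to the printed precision
#' otherwise; `style = "exact"` (the default) keeps full precision and is
#' what every other computation in the package consumes.
#'
#' @param data A data frame with numeric columns `ip` and `ea` (and
#'   typically an `id` column).
#' @param style `"exact"` or `"printed"` (see Details).
#' @return `data` with columns `chi`, `mu_chem`, `eta`, `s`, `omega`,
#'   `gap_ipea` appended.
#' @examples
#' benzil_molecules() |>
#'   dplyr::select(id, ip = ip_vertical, ea = ea_vertical) |>
#'   reactivity_descriptors()
#' @export
reactivity_descriptors <- function(data, style = c("exact", "printed")) {
  style <- match.arg(style)
  check_columns(data, c("ip", "ea"))
  desc <- compute_descriptors(data$ip, data$ea)
  if (style == "printed") {
    chi_r <- round_half_away(desc$chi, 3)
    eta_r <- round_half_away(desc$eta, 3)
    desc <- desc %>% mutate(
      chi = chi_r,
      mu_chem = -chi_r,
      eta = eta_r,
      s = 1 / eta_r,
      omega = chi_r^2 / (2 * eta_r),
      gap_ipea = 2 * eta_r
    )
  }
  dplyr::bind_cols(
    dplyr::select(data, -dplyr::any_of(c("ip", "ea"))),
    desc
  ) %>% as_tibble()
}

#' Frontier-orbital (HOMO-LUMO) gap
#'
#' @param e_homo HOMO energy(ies), eV.
#' @param e_lumo LUMO energy(ies), eV. Must exceed `e_homo` elementwise.
#' @return `e_lumo - e_homo` (positive), eV.
#' @examples
#' orbital_gap(-6.596043, -2.62862)
#' @export
orbital_gap <- function(e_homo, e_lumo) {
  e_homo <- as.numeric(e_homo)
  e_lumo <- as.numeric(e_lumo)
  if (any(e_lumo <= e_homo)) {
    abort("`e_lumo` must exceed `e_homo` for every record.",
          class = "benzilkit_error_ordering")
  }
  e_lumo - e_homo
}

#' Rank molecules by a descriptor value
#'
#' Stable ordering of `id` by `value`; ties are broken by lexicographic id.
#'
#' @param data A data frame with an `id` column (unique) and the column
#'   named by `value`.
#' @param value Name of the numeric column to rank on (string).
#' @param descending If `TRUE`, largest value first.
#' @return Character vector of ids in rank order.
#' @examples
#' benzil_table("descriptors") |> rank_by("s", descending = TRUE)
#' @export
rank_by <- function(data, value, descending = FALSE) {
  check_columns(data, c("id", value))
  check_unique_ids(data$id)
  v <- data[[value]]
  if (any(!is.finite(v))) {
    abort("Ranking values must be finite.", class = "benzilkit_error_input")
  }
  ord <- order(if (descending) -v else v, data$id)
  data$id[ord]
}
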