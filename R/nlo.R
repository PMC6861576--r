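# Nonlinear-optical scalar invariants, au->esu conversion and urea ratios.
#
# Conventions follow standard quantum-chemistry output: the first
# hyperpolarizability scalar is the vector norm of the contracted
# Kleinman-symmetric beta tensor; the second hyperpolarizability scalar is
# the isotropic fifth-average; the polarizability scalar is the mean of the
# diagonal.

beta_component_names <- c("xxx", "xxy", "xxz", "xyy", "xyz", "xzz",
                          "yyy", "yyz", "yzz", "zzz")
gamma_component_names <- c("xxxx", "yyyy", "zzzz", "xxyy", "xxzz", "yyzz")

check_components <- function(x, wanted, what) {
  if (is.null(names(x)) || !all(wanted %in% names(x))) {
    missing <- setdiff(wanted, names(x))
    abort(
      sprintf("%s requires named components %s; missing: %s.",
              what, paste(wanted, collapse = ", "),
              if (length(missing)) paste(missing, collapse = ", ") else "(names absent)"),
      class = "benzilkit_error_input"
    )
  }
  x <- as.numeric(x[wanted])
  if (any(!is.finite(x))) {
    abort(sprintf("%s components must be finite.", what), class = "benzilkit_error_input")
  }
  names(x) <- wanted
  x
}

#' Total first hyperpolarizability from Kleinman components
#'
#' Contracts the 10 independent Kleinman-symmetric components of the
#' first-hyperpolarizability tensor to the standard scalar:
#' \eqn{\beta_x = \beta_{xxx} + \beta_{xyy} + \beta_{xzz}} (and cyclically
#' for y, z), then \eqn{\beta_{tot} = \sqrt{\beta_x^2+\beta_y^2+\beta_z^2}}.
#' Rotation invariant.
#'
#' @param beta Named numeric vector with components `xxx, xxy, xxz, xyy,
#'   xyz, xzz, yyy, yyz, yzz, zzz` (atomic units).
#' @return Nonnegative scalar, atomic units.
#' @examples
#' beta_total(c(xxx = 3, xyy = 4, xxy = 0, xxz = 0, xyz = 0,
#'              xzz = 0, yyy = 0, yyz = 0, yzz = 0, zzz = 0))
#' @export
beta_total <- function(beta) {
  b <- check_components(beta, beta_component_names, "beta_total()")
  bx <- b["xxx"] + b["xyy"] + b["xzz"]
  by <- b["yyy"] + b["xxy"] + b["yzz"]
  bz <- b["zzz"] + b["xxz"] + b["yyz"]
  unname(sqrt(bx^2 + by^2 + bz^2))
}

#' Isotropic average second hyperpolarizability
#'
#' \eqn{\langle\gamma\rangle = (\gamma_{xxxx} + \gamma_{yyyy} +
#' \gamma_{zzzz} + 2\gamma_{xxyy} + 2\gamma_{xxzz} + 2\gamma_{yyzz})/5}.
#' May be negative.
#'
#' @param gamma Named numeric vector with components `xxxx, yyyy, zzzz,
#'   xxyy, xxzz, yyzz` (atomic units).
#' @return Scalar, atomic units.
#' @examples
#' gamma_average(c(xxxx = 5, yyyy = 5, zzzz = 5, xxyy = 0, xxzz = 0, yyzz = 0))
#' @export
gamma_average <- function(gamma) {
  g <- check_components(gamma, gamma_component_names, "gamma_average()")
  unname((g["xxxx"] + g["yyyy"] + g["zzzz"] +
            2 * (g["xxyy"] + g["xxzz"] + g["yyzz"])) / 5)
}

#' Mean polarizability from diagonal components
#'
#' @param alpha Named numeric vector with components `xx, yy, zz` (atomic
#'   units).
#' @return \eqn{(\alpha_{xx}+\alpha_{yy}+\alpha_{zz})/3}, atomic units.
#' @examples
#' alpha_mean(c(xx = 10, yy = 12, zz = 14))
#' @export
alpha_mean <- function(alpha) {
  a <- check_components(alpha, c("xx", "yy", "zz"), "alpha_mean()")
  unname(mean(a))
}

# esu per atomic unit
au_esu_factors <- c(alpha = 1.4819e-25, beta = 8.6393e-33, gamma = 5.0367e-40)

#' Convert a polarizability scalar from atomic units to esu
#'
#' @param value Scalar(s) in atomic units.
#' @param kind `"alpha"`, `"beta"` or `"gamma"` (selects the conversion
#'   factor: 1.4819e-25, 8.6393e-33 or 5.0367e-40 esu per au).
#' @return Value(s) in esu.
#' @examples
#' au_to_esu(1, "beta")
#' @export
au_to_esu <- function(value, kind = c("alpha", "beta", "gamma")) {
  if (!is.character(kind) || !all(kind %in% names(au_esu_factors))) {
    abort("`kind` must be one of 'alpha', 'beta', 'gamma'.",
          class = "benzilkit_error_input")
  }
  kind <- match.arg(kind)
  as.numeric(value) * au_esu_factors[[kind]]
}

#' Fold-ratio of a hyperpolarizability to a reference material
#'
#' Divides by the reference and rounds half away from zero to an integer
#' fold, the convention behind statements like "x times that of urea". The
#' default reference is the urea first hyperpolarizability 0.13e-30 esu.
#'
#' @param beta_esu Hyperpolarizability value(s), esu.
#' @param reference_esu Positive reference value, esu (default 0.13e-30).
#' @return Integer fold(s).
#' @examples
#' ratio_to_reference(8.295e-30)
#' @export
ratio_to_reference <- function(beta_esu, reference_esu = 0.13e-30) {
  if (!is.finite(reference_esu) || reference_esu <= 0) {
    abort("`reference_esu` must be positive.", class = "benzilkit_error_domain")
  }
  as.integer(round_half_away(as.numeric(beta_esu) / reference_esu))
}

#' NLO summary table with urea-referenced ratios
#'
#' Appends the integer urea fold-ratio to an NLO scalar table.
#'
#' @param data A data frame with a `beta_esu30` column (first
#'   hyperpolarizability in units of 1e-30 esu), e.g. `benzil_table("nlo")`.
#' @param reference_esu Reference hyperpolarizability, esu.
#' @return `data` with a `urea_ratio` integer column appended.
#' @examples
#' benzil_table("nlo") |> nlo_table()
#' @export
nlo_table <- function(data, reference_esu = 0.13e-30) {
  check_columns(data, "beta_esu30")
  data %>%
    mutate(urea_ratio = ratio_to_reference(.data$beta_esu30 * 1e-30, reference_esu)) %>%
    as_tibble()
}
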