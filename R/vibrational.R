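#' Scale calculated harmonic wavenumbers
#'
#' Multiplies calculated (harmonic) wavenumbers by an empirical scaling
#' factor that corrects systematic overestimation of fundamentals; the
#' default 0.9613 is the standard B3LYP factor. Scaling is guarded against
#' being applied twice: the returned table carries `scaled = TRUE` and
#' re-scaling such a table is an error.
#'
#' @param modes A data frame of calculated modes with a `wavenumber` column
#'   (cm^-1) and optionally a logical `scaled` column (assumed `FALSE` when
#'   absent).
#' @param factor Positive dimensionless scaling factor (default 0.9613).
#' @return `modes` with wavenumbers multiplied by `factor` and
#'   `scaled = TRUE`.
#' @examples
#' apply_scaling(tibble::tibble(wavenumber = c(1000, 3200)))
#' @export
apply_scaling <- function(modes, factor = 0.9613) {
  check_columns(modes, "wavenumber", arg = "modes")
  if (!is.finite(factor) || factor <= 0) {
    abort("`factor` must be positive.", class = "benzilkit_error_domain")
  }
  if (nrow(modes) == 0) {
    modes$scaled <- logical(0)
    return(as_tibble(modes))
  }
  if (any(modes$wavenumber <= 0)) {
    abort("Wavenumbers must be > 0.", class = "benzilkit_error_validation")
  }
  if ("scaled" %in% names(modes) && any(modes$scaled)) {
    abort("Modes are already scaled; re-scaling a scaled list is an error.",
          class = "benzilkit_error_state")
  }
  modes %>%
    mutate(wavenumber = .data$wavenumber * factor, scaled = TRUE) %>%
    as_tibble()
}

#' Pair calculated modes with observed bands
#'
#' Builds calculated/observed band pairs either row-wise (`"assigned"`:
#' the inputs are already aligned, as in published assignment tables) or by
#' greedy nearest-wavenumber matching within a window (`"nearest"`: all
#' candidate pairs within `window` cm^-1 are considered in ascending order
#' of distance, and each calculated mode and each observed band is used at
#' most once).
#'
#' @param modes Data frame of calculated modes with `wavenumber` (cm^-1);
#'   an `assignment` column is carried through if present.
#' @param obs Data frame of observed bands with `wavenumber` (cm^-1) and
#'   optionally `technique` (`"IR"` or `"Raman"`).
#' @param mode `"assigned"` or `"nearest"`.
#' @param window Matching window for nearest mode, cm^-1 (default 30).
#' @return A tibble of pairs with columns `calc`, `obs`, `technique`,
#'   `assignment`; unmatched observed bands are reported in the
#'   `"unmatched_obs"` attribute (nearest mode).
#' @examples
#' pair_bands(tibble::tibble(wavenumber = 100),
#'            tibble::tibble(wavenumber = 103), mode = "nearest", window = 5)
#' @export
pair_bands <- function(modes, obs, mode = c("assigned", "nearest"), window = 30) {
  mode <- match.arg(mode)
  check_columns(modes, "wavenumber", arg = "modes")
  check_columns(obs, "wavenumber", arg = "obs")
  technique <- if ("technique" %in% names(obs)) obs$technique else rep(NA_character_, nrow(obs))
  assignment <- if ("assignment" %in% names(modes)) modes$assignment else rep(NA_character_, nrow(modes))

  if (mode == "assigned") {
    if (nrow(modes) != nrow(obs)) {
      abort("Assigned mode expects row-aligned `modes` and `obs` of equal length.",
            class = "benzilkit_error_input")
    }
    keep <- is.finite(modes$wavenumber) & is.finite(obs$wavenumber)
    return(tibble(
      calc = modes$wavenumber[keep],
      obs = obs$wavenumber[keep],
      technique = technique[keep],
      assignment = assignment[keep]
    ))
  }

  if (!is.finite(window) || window <= 0) {
    abort("`window` must be > 0 in nearest mode.", class = "benzilkit_error_domain")
  }
  if (nrow(obs) == 0 || nrow(modes) == 0) {
    out <- tibble(calc = numeric(), obs = numeric(),
                  technique = character(), assignment = character())
    attr(out, "unmatched_obs") <- obs$wavenumber
    return(out)
  }
  cand <- tidyr::expand_grid(i = seq_len(nrow(modes)), j = seq_len(nrow(obs))) %>%
    mutate(dist = abs(modes$wavenumber[.data$i] - obs$wavenumber[.data$j])) %>%
    filter(.data$dist <= window) %>%
    arrange(.data$dist, .data$i, .data$j)
  used_i <- logical(nrow(modes))
  used_j <- logical(nrow(obs))
  pick <- integer(0)
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (!used_i[i] && !used_j[j]) {
      used_i[i] <- TRUE
      used_j[j] <- TRUE
      pick <- c(pick, k)
    }
  }
  sel <- cand[pick, , drop = FALSE]
  out <- tibble(
    calc = modes$wavenumber[sel$i],
    obs = obs$wavenumber[sel$j],
    technique = technique[sel$j],
    assignment = assignment[sel$i]
  ) %>% arrange(.data$calc)
  attr(out, "unmatched_obs") <- obs$wavenumber[!used_j]
  out
}

#' Root-mean-square deviation of band pairs
#'
#' \eqn{RMSD = \sqrt{mean((calc - obs)^2)}} over calculated/observed pairs,
#' cm^-1. Invariant to pair order and to swapping calc and obs.
#'
#' @param pairs A data frame with numeric columns `calc` and `obs`.
#' @return RMSD, cm^-1.
#' @examples
#' band_rmsd(tibble::tibble(calc = c(10, 20), obs = c(13, 16)))
#' @export
band_rmsd <- function(pairs) {
  check_columns(pairs, c("calc", "obs"), arg = "pairs")
  if (nrow(pairs) == 0) {
    abort("Need at least one band pair.", class = "benzilkit_error_input")
  }
  sqrt(mean((pairs$calc - pairs$obs)^2))
}

#' Per-technique calc-vs-obs agreement for an assignment table
#'
#' Takes a row-wise assignment table in the packaged fixture layout
#' (columns `calc`, `obs_ir`, `obs_raman`; see [benzil_vibrations()]),
#' builds assigned-mode pairs separately for IR and Raman, and reports the
#' pair count and RMSD per technique. Techniques with no observed bands are
#' dropped.
#'
#' @param data Assignment table with columns `calc`, `obs_ir`, `obs_raman`.
#' @return A tibble with columns `technique`, `n_pairs`, `rmsd`.
#' @examples
#' benzil_vibrations("BZL") |> vibrational_rmsd()
#' @export
vibrational_rmsd <- function(data) {
  check_columns(data, c("calc", "obs_ir", "obs_raman"))
  per_technique <- function(obs_col, technique) {
    pairs <- pair_bands(
      modes = tibble(wavenumber = data$calc,
                     assignment = if ("assignment" %in% names(data)) data$assignment else NA_character_),
      obs = tibble(wavenumber = data[[obs_col]], technique = technique),
      mode = "assigned"
    )
    if (nrow(pairs) == 0) return(NULL)
    tibble(technique = technique, n_pairs = nrow(pairs), rmsd = band_rmsd(pairs))
  }
  dplyr::bind_rows(per_technique("obs_ir", "IR"), per_technique("obs_raman", "Raman"))
}

#' Assigned-mode band pairs for one technique from an assignment table
#'
#' Convenience extractor used by the RMSD report and the plots: keeps the
#' fixture rows where both the calculated and the chosen observed column
#' are present.
#'
#' @param data Assignment table (see [benzil_vibrations()]).
#' @param technique `"IR"` or `"Raman"`.
#' @return A pair tibble as from [pair_bands()].
#' @examples
#' vibrational_pairs(benzil_vibrations("BZL"), "IR")
#' @export
vibrational_pairs <- function(data, technique = c("IR", "Raman")) {
  technique <- match.arg(technique)
  check_columns(data, c("calc", "obs_ir", "obs_raman"))
  obs_col <- if (technique == "IR") "obs_ir" else "obs_raman"
  pair_bands(
    modes = tibble(wavenumber = data$calc,
                   assignment = if ("assignment" %in% names(data)) data$assignment else NA_character_),
    obs = tibble(wavenumber = data[[obs_col]], technique = technique),
    mode = "assigned"
  )
}
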