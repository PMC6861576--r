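# Seeded synthetic-data generators. Every generator is a pure function of
# its config: a fixed seed yields byte-identical output, and each generator
# draws from its own named stream so adding a generator never perturbs the
# output of an existing one.

stream_seed <- function(seed, stream) {
  # distinct sub-seed per named stream, kept well below 2^31
  (abs(as.integer(seed)) %% 1000000L) * 1009L + sum(utf8ToInt(stream))
}

with_stream <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, stream))
  force(code)
}

check_range <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2 || any(!is.finite(x)) || x[1] > x[2]) {
    abort(sprintf("`%s` must be a nonempty numeric interval c(lo, hi).", name),
          class = "benzilkit_error_config")
  }
  invisible(x)
}

#' Configuration for the synthetic-data generators
#'
#' Defaults mirror the study conditions: a five-dye series with vertical IP
#' strictly above EA in the 8-9 / 5.5-6.2 eV windows of the benzil series,
#' one dominant excitation per dye in the near-UV with moderate-to-strong
#' oscillator strength, vibrational observation noise of 5 cm^-1 (the
#' magnitude of the study's IR RMSDs), two-fold torsional wells of 8-18
#' kJ/mol on a 10 degree grid, and docking blocks of 10 conformations.
#'
#' @param seed Integer seed; fixed seed implies byte-identical output.
#' @param n_molecules Number of molecules to generate.
#' @param ip_range,ea_range Vertical IP / EA intervals, eV. `ip_range`
#'   must lie strictly above `ea_range`.
#' @param lambda_range Absorption-maximum interval, nm.
#' @param f_range Oscillator-strength interval (nonnegative).
#' @param vib_noise_sigma Gaussian noise of observed bands, cm^-1, `>= 0`.
#' @param vib_n Number of vibrational modes.
#' @param torsion_amplitude_range Torsional barrier interval, kJ/mol.
#' @param torsion_periodicity Integer periodicity of the torsional well.
#' @param grid_step Torsion grid step, degrees; must divide 360.
#' @param docking_block_size Conformations per docking block.
#' @return A validated `generator_config` list.
#' @examples
#' generator_config(seed = 1)
#' @export
generator_config <- function(seed = 1L,
                             n_molecules = 5L,
                             ip_range = c(8.0, 8.8),
                             ea_range = c(5.5, 6.2),
                             lambda_range = c(260, 300),
                             f_range = c(0.5, 1.1),
                             vib_noise_sigma = 5,
                             vib_n = 200L,
                             torsion_amplitude_range = c(8, 18),
                             torsion_periodicity = 2L,
                             grid_step = 10,
                             docking_block_size = 10L) {
  check_range(ip_range, "ip_range")
  check_range(ea_range, "ea_range")
  check_range(lambda_range, "lambda_range")
  check_range(f_range, "f_range")
  check_range(torsion_amplitude_range, "torsion_amplitude_range")
  if (ip_range[1] <= ea_range[2]) {
    abort("`ip_range` must lie strictly above `ea_range`.",
          class = "benzilkit_error_config")
  }
  if (f_range[1] < 0 || lambda_range[1] <= 0) {
    abort("Oscillator strengths must be >= 0 and wavelengths > 0.",
          class = "benzilkit_error_config")
  }
  if (!is.finite(vib_noise_sigma) || vib_noise_sigma < 0) {
    abort("`vib_noise_sigma` must be >= 0.", class = "benzilkit_error_config")
  }
  if (n_molecules < 0 || vib_n < 1 || docking_block_size < 1) {
    abort("Counts must be positive (n_molecules may be 0).",
          class = "benzilkit_error_config")
  }
  if (360 %% grid_step != 0) {
    abort("`grid_step` must divide 360.", class = "benzilkit_error_config")
  }
  structure(
    list(seed = as.integer(seed), n_molecules = as.integer(n_molecules),
         ip_range = ip_range, ea_range = ea_range,
         lambda_range = lambda_range, f_range = f_range,
         vib_noise_sigma = vib_noise_sigma, vib_n = as.integer(vib_n),
         torsion_amplitude_range = torsion_amplitude_range,
         torsion_periodicity = as.integer(torsion_periodicity),
         grid_step = grid_step,
         docking_block_size = as.integer(docking_block_size)),
    class = "generator_config"
  )
}

#' Generate synthetic molecule summaries with known ground truth
#'
#' Draws molecules satisfying every data-model invariant. The returned
#' table carries the ground-truth descriptor values (`truth_chi`,
#' `truth_eta`, `truth_omega`, computed here by independent arithmetic at
#' draw time) so descriptor-recovery tests can compare against them.
#'
#' @param config A [generator_config()].
#' @return A tibble with columns `id`, `e_homo`, `e_lumo`, `ip_vertical`,
#'   `ea_vertical`, `lambda_max_nm`, `f`, `dipole_debye`, `truth_chi`,
#'   `truth_eta`, `truth_omega`.
#' @examples
#' generate_molecules(generator_config(seed = 1))
#' @export
generate_molecules <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_molecules
  if (n == 0) {
    return(tibble(id = character(), e_homo = numeric(), e_lumo = numeric(),
                  ip_vertical = numeric(), ea_vertical = numeric(),
                  lambda_max_nm = numeric(), f = numeric(),
                  dipole_debye = numeric(), truth_chi = numeric(),
                  truth_eta = numeric(), truth_omega = numeric()))
  }
  with_stream(config$seed, "molecules", {
    ip <- runif(n, config$ip_range[1], config$ip_range[2])
    ea <- runif(n, config$ea_range[1], config$ea_range[2])
    e_homo <- runif(n, -7.2, -6.2)
    e_lumo <- runif(n, -3.0, -1.5)
    lambda <- runif(n, config$lambda_range[1], config$lambda_range[2])
    f <- runif(n, config$f_range[1], config$f_range[2])
    dip <- runif(n, 0.5, 3.5)
    tibble(
      id = sprintf("SYN%02d", seq_len(n)),
      e_homo = e_homo, e_lumo = e_lumo,
      ip_vertical = ip, ea_vertical = ea,
      lambda_max_nm = lambda, f = f, dipole_debye = dip,
      truth_chi = (ip + ea) / 2,
      truth_eta = (ip - ea) / 2,
      truth_omega = ((ip + ea) / 2)^2 / (ip - ea)
    )
  })
}

#' Generate a synthetic calculated/observed vibrational set
#'
#' Calculated harmonic modes paired with observed bands built as
#' `obs = factor * calc + N(0, sigma)`; assigned-mode pairing of the scaled
#' modes against the bands therefore has RMSD concentrated near `sigma`.
#'
#' @param config A [generator_config()] (`vib_n` modes, noise
#'   `vib_noise_sigma`).
#' @param factor Scaling factor applied to the harmonic wavenumbers when
#'   constructing the observations (default 0.9613).
#' @return A list with `modes` (unscaled calculated modes: `wavenumber`,
#'   `ir_intensity`, `raman_activity`, `assignment`, `scaled = FALSE`) and
#'   `bands` (observed: `wavenumber`, `technique = "IR"`).
#' @examples
#' set <- generate_vibrational_set(generator_config(seed = 7))
#' band_rmsd(tibble::tibble(calc = apply_scaling(set$modes)$wavenumber,
#'                          obs = set$bands$wavenumber))
#' @export
generate_vibrational_set <- function(config, factor = 0.9613) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$vib_n
  with_stream(config$seed, "vibrational", {
    calc <- sort(runif(n, 200, 3300))
    obs <- factor * calc + rnorm(n, 0, config$vib_noise_sigma)
    list(
      modes = tibble(
        wavenumber = calc,
        ir_intensity = stats::rexp(n, 1 / 50),
        raman_activity = stats::rexp(n, 1 / 30),
        assignment = sprintf("mode%03d", seq_len(n)),
        scaled = FALSE
      ),
      bands = tibble(wavenumber = obs, technique = "IR")
    )
  })
}

#' Generate a cosine torsional potential-energy profile
#'
#' Builds `A/2 * (1 - cos(k * (theta - phase)))` on a regular grid over
#' [0, 360). When `phase` and `phase + 180/k` lie on the grid (the case for
#' the defaults), the grid hits both extrema exactly and the recovered
#' barrier equals `amplitude` to machine precision.
#'
#' @param amplitude Barrier height A, kJ/mol, `>= 0`.
#' @param periodicity Integer k `>= 1`.
#' @param phase_deg Angle of the global minimum, degrees.
#' @param grid_step Grid step, degrees; must divide 360.
#' @return A profile tibble (`angle_deg`, `energy`).
#' @examples
#' barrier_height(generate_torsion_profile(16.3175, 2, 130, 10))
#' @export
generate_torsion_profile <- function(amplitude, periodicity = 2L, phase_deg = 130,
                                     grid_step = 10) {
  if (!is.finite(amplitude) || amplitude < 0) {
    abort("`amplitude` must be >= 0.", class = "benzilkit_error_config")
  }
  if (periodicity < 1 || periodicity != round(periodicity)) {
    abort("`periodicity` must be an integer >= 1.", class = "benzilkit_error_config")
  }
  if (360 %% grid_step != 0) {
    abort("`grid_step` must divide 360.", class = "benzilkit_error_config")
  }
  angle <- seq(0, 360 - grid_step, by = grid_step)
  tibble(
    angle_deg = angle,
    energy = amplitude / 2 * (1 - cos(periodicity * (angle - phase_deg) * pi / 180))
  )
}

#' Generate a synthetic ranked docking score table
#'
#' One block of `docking_block_size` conformations per receptor-ligand
#' pair, sorted by global energy so the result passes the same validation
#' as parsed server output.
#'
#' @param config A [generator_config()].
#' @param receptors,ligands Labels for the blocks.
#' @return A docking tibble in the [read_docking_scores()] layout.
#' @examples
#' generate_docking_table(generator_config(seed = 3), "R1", c("L1", "L2"))
#' @export
generate_docking_table <- function(config, receptors = "R1",
                                   ligands = c("L1", "L2", "L3")) {
  stopifnot(inherits(config, "generator_config"))
  m <- config$docking_block_size
  with_stream(config$seed, "docking", {
    blocks <- tidyr::expand_grid(receptor = receptors, ligand = ligands)
    purrr::pmap_dfr(blocks, function(receptor, ligand) {
      global <- sort(runif(m, -40, -10))
      tibble(
        receptor = receptor, ligand = ligand, rank = seq_len(m),
        global_energy = global,
        attractive_vdw = runif(m, -20, -5),
        repulsive_vdw = runif(m, 0, 15),
        ace = runif(m, -12, 1)
      )
    })
  })
}
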