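test_that("generators are pure functions of their config", {
  cfg <- generator_config(seed = 1)
  expect_identical(generate_molecules(cfg), generate_molecules(cfg))
  expect_identical(generate_vibrational_set(cfg), generate_vibrational_set(cfg))
  expect_identical(generate_docking_table(cfg), generate_docking_table(cfg))
  expect_identical(generate_torsion_profile(7, 2, 130, 10),
                   generate_torsion_profile(7, 2, 130, 10))
  # different seeds give different draws
  expect_false(identical(generate_molecules(cfg),
                         generate_molecules(generator_config(seed = 2))))
})

test_that("generated molecules satisfy the data-model invariants with recorded truth", {
  mols <- generate_molecules(generator_config(seed = 1, n_molecules = 5))
  expect_equal(nrow(mols), 5)
  expect_true(all(mols$e_homo < mols$e_lumo))
  expect_true(all(mols$ip_vertical > mols$ea_vertical))
  expect_true(all(mols$lambda_max_nm > 0 & mols$f >= 0))
  d <- compute_descriptors(mols$ip_vertical, mols$ea_vertical)
  expect_equal(d$chi, mols$truth_chi, tolerance = 0)
  expect_equal(d$eta, mols$truth_eta, tolerance = 0)
  expect_equal(d$omega, mols$truth_omega, tolerance = 0)

  empty <- generate_molecules(generator_config(seed = 1, n_molecules = 0))
  expect_equal(nrow(empty), 0)
})

test_that("config validation rejects inconsistent ranges", {
  expect_error(generator_config(ip_range = c(5, 6), ea_range = c(5.5, 6.2)),
               class = "benzilkit_error_config")
  expect_error(generator_config(vib_noise_sigma = -1),
               class = "benzilkit_error_config")
  expect_error(generator_config(ip_range = c(9, 8)),
               class = "benzilkit_error_config")
  expect_error(generator_config(grid_step = 7),
               class = "benzilkit_error_config")
  expect_error(generate_torsion_profile(-1), class = "benzilkit_error_config")
  expect_error(generate_torsion_profile(1, periodicity = 0),
               class = "benzilkit_error_config")
})

test_that("noiseless synthetic observations pair with zero RMSD", {
  cfg <- generator_config(seed = 3, vib_noise_sigma = 0, vib_n = 50)
  vib <- generate_vibrational_set(cfg)
  scaled <- apply_scaling(vib$modes)
  pairs <- pair_bands(scaled, vib$bands, mode = "assigned")
  expect_equal(nrow(pairs), 50)
  expect_equal(band_rmsd(pairs), 0)
})

test_that("synthetic RMSD concentrates near the generating noise level", {
  cfg <- generator_config(seed = 7, vib_noise_sigma = 5, vib_n = 200)
  vib <- generate_vibrational_set(cfg)
  pairs <- pair_bands(apply_scaling(vib$modes), vib$bands, mode = "assigned")
  expect_equal(nrow(pairs), 200)
  r <- band_rmsd(pairs)
  expect_gt(r, 4.25)
  expect_lt(r, 5.75)
})

test_that("synthetic docking blocks pass the same validation as parsed tables", {
  cfg <- generator_config(seed = 9)
  dock <- generate_docking_table(cfg, receptors = c("R1", "R2"),
                                 ligands = c("L1", "L2"))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dock, path)
  parsed <- read_docking_scores(path)
  expect_equal(nrow(parsed), 2 * 2 * cfg$docking_block_size)
  expect_equal(best_complex(dplyr::filter(parsed, receptor == "R1"))$value,
               min(dock$global_energy[dock$receptor == "R1"]))
})

test_that("fixture regeneration is byte-identical under a fixed seed", {
  cfg <- generator_config(seed = 5)
  dir_a <- withr::local_tempdir()
  dir_b <- withr::local_tempdir()
  write_suite <- function(dir) {
    readr::write_csv(generate_molecules(cfg), file.path(dir, "mols.csv"))
    vib <- generate_vibrational_set(cfg)
    readr::write_csv(vib$modes, file.path(dir, "modes.csv"))
    readr::write_csv(vib$bands, file.path(dir, "bands.csv"))
    readr::write_csv(generate_docking_table(cfg), file.path(dir, "dock.csv"))
  }
  write_suite(dir_a)
  write_suite(dir_b)
  for (f in c("mols.csv", "modes.csv", "bands.csv", "dock.csv")) {
    expect_identical(readBin(file.path(dir_a, f), "raw", file.size(file.path(dir_a, f))),
                     readBin(file.path(dir_b, f), "raw", file.size(file.path(dir_b, f))))
  }
})

test_that("generator streams are independent: order of calls does not matter", {
  cfg <- generator_config(seed = 4)
  m1 <- generate_molecules(cfg)
  v1 <- generate_vibrational_set(cfg)
  v2 <- generate_vibrational_set(cfg)
  m2 <- generate_molecules(cfg)
  expect_identical(m1, m2)
  expect_identical(v1, v2)
})
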