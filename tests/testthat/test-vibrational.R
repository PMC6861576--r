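test_that("scaling multiplies wavenumbers once and only once", {
  modes <- tibble::tibble(wavenumber = c(1000, 3200))
  scaled <- apply_scaling(modes)
  expect_equal(scaled$wavenumber, c(961.3, 3076.16))
  expect_true(all(scaled$scaled))
  expect_error(apply_scaling(scaled), class = "benzilkit_error_state")

  empty <- apply_scaling(modes[0, ])
  expect_equal(nrow(empty), 0)

  identity <- apply_scaling(modes, factor = 1)
  expect_equal(identity$wavenumber, modes$wavenumber)
  expect_true(all(identity$scaled))

  expect_error(apply_scaling(modes, factor = 0), class = "benzilkit_error_domain")
})

test_that("assigned-mode pairing keeps exactly the complete fixture rows", {
  bzl <- benzil_vibrations("BZL")
  ir <- vibrational_pairs(bzl, "IR")
  expect_equal(nrow(ir), sum(!is.na(bzl$calc) & !is.na(bzl$obs_ir)))
  expect_equal(nrow(ir), 26)
  raman <- vibrational_pairs(bzl, "Raman")
  expect_equal(nrow(raman), 22)
  expect_true(all(ir$technique == "IR"))
})

test_that("nearest-mode pairing is greedy within the window", {
  one <- pair_bands(tibble::tibble(wavenumber = 100),
                    tibble::tibble(wavenumber = 103),
                    mode = "nearest", window = 5)
  expect_equal(nrow(one), 1)
  expect_equal(one$calc, 100)
  expect_equal(one$obs, 103)

  none <- pair_bands(tibble::tibble(wavenumber = c(100, 200)),
                     tibble::tibble(wavenumber = numeric()),
                     mode = "nearest", window = 5)
  expect_equal(nrow(none), 0)

  # two obs compete for one calc: the closer wins, the other reports unmatched
  comp <- pair_bands(tibble::tibble(wavenumber = 100),
                     tibble::tibble(wavenumber = c(104, 98)),
                     mode = "nearest", window = 10)
  expect_equal(nrow(comp), 1)
  expect_equal(comp$obs, 98)
  expect_equal(attr(comp, "unmatched_obs"), 104)

  expect_error(pair_bands(tibble::tibble(wavenumber = 1),
                          tibble::tibble(wavenumber = 1),
                          mode = "nearest", window = 0),
               class = "benzilkit_error_domain")
})

test_that("rmsd matches the hand oracle and its invariances", {
  expect_equal(band_rmsd(tibble::tibble(calc = c(5, 9), obs = c(5, 9))), 0)
  expect_equal(band_rmsd(tibble::tibble(calc = c(10, 20), obs = c(13, 16))),
               sqrt((9 + 16) / 2), tolerance = 1e-10)
  expect_equal(round(band_rmsd(tibble::tibble(calc = c(10, 20), obs = c(13, 16))), 4),
               3.5355)
  expect_error(band_rmsd(tibble::tibble(calc = numeric(), obs = numeric())),
               class = "benzilkit_error_input")

  set.seed(21)
  pairs <- tibble::tibble(calc = runif(30, 100, 3000))
  pairs$obs <- pairs$calc + rnorm(30, 0, 8)
  shuffled <- pairs[sample(nrow(pairs)), ]
  expect_equal(band_rmsd(shuffled), band_rmsd(pairs))
  swapped <- tibble::tibble(calc = pairs$obs, obs = pairs$calc)
  expect_equal(band_rmsd(swapped), band_rmsd(pairs))
})

test_that("per-technique RMSD report lands near the published values", {
  report <- vibrational_rmsd(benzil_vibrations("BZL"))
  expect_equal(report$technique, c("IR", "Raman"))
  ir <- report$rmsd[report$technique == "IR"]
  expect_gt(ir, 4.8)
  expect_lt(ir, 5.4)
  # no Raman bands reported for the dibromo dye: only the IR row appears
  dbb <- vibrational_rmsd(benzil_vibrations("DBB"))
  expect_equal(dbb$technique, "IR")
})

test_that("pairing operates on scaled wavenumbers (scale first, then pair)", {
  # documented non-property: scaling and pairing only commute if the window
  # scales too, so the supported workflow is apply_scaling() before pair_bands()
  modes <- tibble::tibble(wavenumber = 1000)
  obs <- tibble::tibble(wavenumber = 961)
  raw <- pair_bands(modes, obs, mode = "nearest", window = 5)
  expect_equal(nrow(raw), 0)
  scaled_first <- pair_bands(apply_scaling(modes), obs, mode = "nearest", window = 5)
  expect_equal(nrow(scaled_first), 1)
  expect_equal(scaled_first$calc, 961.3)
})
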