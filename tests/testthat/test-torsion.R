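test_that("relative conversion shifts the minimum to zero and converts hartree", {
  prof <- tibble::tibble(angle_deg = c(0, 90), energy = c(0, 0.01))
  rel <- torsion_relative(prof, unit_in = "hartree")
  expect_equal(rel$energy, c(0, 26.255))

  already <- generate_torsion_profile(10, 2, 130, 10)
  expect_equal(torsion_relative(already)$energy, already$energy)

  const <- tibble::tibble(angle_deg = seq(0, 350, 10), energy = 7.5)
  expect_equal(torsion_relative(const)$energy, rep(0, 36))

  expect_error(torsion_relative(const[0, ]), class = "benzilkit_error_input")
})

test_that("grid extrema recover the analytic well of a two-fold cosine", {
  # A(1 - cos 2(theta-130)) with A = 8.158: max where theta-130 = +/-90
  prof <- tibble::tibble(
    angle_deg = seq(0, 350, 10),
    energy = 8.158 * (1 - cos(2 * (seq(0, 350, 10) - 130) * pi / 180))
  )
  ext <- torsion_extrema(prof)
  expect_equal(ext$angle_deg[ext$extremum == "min"], 130)
  expect_equal(ext$angle_deg[ext$extremum == "max"], 40)
  expect_false(any(ext$flat))

  parab <- tibble::tibble(angle_deg = seq(0, 350, 10),
                          energy = (seq(0, 350, 10) - 180)^2)
  pe <- torsion_extrema(parab)
  expect_equal(pe$angle_deg[pe$extremum == "min"], 180)

  flat <- tibble::tibble(angle_deg = seq(0, 350, 10), energy = 1)
  expect_warning(fe <- torsion_extrema(flat), "Flat")
  expect_equal(fe$energy[1], fe$energy[2])
  expect_true(all(fe$flat))
})

test_that("barrier height is max minus min and shift/rotation invariant", {
  prof <- generate_torsion_profile(16.3175, 2, 130, 10)
  expect_equal(barrier_height(prof), 16.3175, tolerance = 1e-9)
  expect_equal(barrier_height(tibble::tibble(angle_deg = seq(0, 350, 10),
                                             energy = 3)), 0)

  shifted <- dplyr::mutate(prof, energy = energy + 123.4)
  expect_equal(barrier_height(shifted), barrier_height(prof))

  # rotating the periodic grid by a grid multiple preserves the barrier
  rotated <- dplyr::mutate(prof, angle_deg = (angle_deg + 90) %% 360) |>
    dplyr::arrange(angle_deg)
  expect_equal(barrier_height(rotated), barrier_height(prof))
})

test_that("published barrier amplitudes order the series DFB > DCB > BZL > DBB > DMB", {
  meta <- benzil_table("torsion_metadata")
  profs <- purrr::map2_dfr(meta$id, meta$barrier_kj_mol, function(id, a) {
    dplyr::mutate(generate_torsion_profile(a, 2, 130, 10), id = id)
  })
  ordered <- order_barriers(profs)
  expect_equal(ordered$id, c("DFB", "DCB", "BZL", "DBB", "DMB"))
  expect_equal(ordered$barrier_kj_mol,
               sort(meta$barrier_kj_mol, decreasing = TRUE), tolerance = 1e-9)

  one <- order_barriers(dplyr::mutate(generate_torsion_profile(5, 2, 130, 10), id = "X"))
  expect_equal(one$id, "X")

  tied <- dplyr::bind_rows(
    dplyr::mutate(generate_torsion_profile(5, 2, 130, 10), id = "B"),
    dplyr::mutate(generate_torsion_profile(5, 2, 130, 10), id = "A")
  )
  expect_equal(order_barriers(tied)$id, c("A", "B"))
  expect_error(order_barriers(tied[0, ]), class = "benzilkit_error_input")
})

test_that("barrier and extrema are recovered across random well parameters", {
  set.seed(31)
  for (rep in 1:50) {
    A <- runif(1, 1, 25)
    k <- sample(c(1L, 2L, 3L, 6L), 1)  # 180/k on the 10-degree grid
    theta0 <- sample(seq(0, 350, 10), 1)
    prof <- generate_torsion_profile(A, k, theta0, 10)
    expect_equal(barrier_height(prof), A, tolerance = 1e-9)
    ext <- torsion_extrema(prof)
    a_min <- ext$angle_deg[ext$extremum == "min"]
    a_max <- ext$angle_deg[ext$extremum == "max"]
    # recovered angles sit in the analytic extremum sets of the k-fold well
    expect_equal(cos(k * (a_min - theta0) * pi / 180), 1, tolerance = 1e-9)
    expect_equal(cos(k * (a_max - theta0) * pi / 180), -1, tolerance = 1e-9)
  }
})

test_that("profile csv reader honours the unit header", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# unit: hartree", "angle_deg,energy", "0,0", "90,0.01", "180,0"),
             path)
  prof <- read_torsion_profile(path)
  expect_equal(max(prof$energy), 26.255)
})
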