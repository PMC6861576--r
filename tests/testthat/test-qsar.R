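test_that("a two-point one-predictor fit is the line through the points", {
  data <- tibble::tibble(x = c(0, 1), y = c(1, 3))
  fit <- qsar_fit(data, response = "y", predictors = "x")
  expect_equal(unname(fit$coefficients["x"]), 2)
  expect_equal(unname(fit$coefficients["intercept"]), 1)
  expect_true(fit$exact_fit)
  expect_equal(predict(fit, tibble::tibble(x = 5)), 11)
})

test_that("square fits on the study table interpolate the binding energies", {
  tbl <- benzil_table("qsar")
  for (r in c("3WMT", "2H4Z", "2EEP")) {
    fit <- qsar_fit(tbl, response = paste0("be_", r), receptor = r)
    expect_true(fit$exact_fit)
    expect_lt(max(abs(fit$residuals)), 1e-8)
    expect_equal(predict(fit, tbl), tbl[[paste0("be_", r)]], tolerance = 1e-8)
  }
  # BZL prediction from the refit model equals its published binding energy
  fit3 <- qsar_fit(tbl, "be_3WMT")
  expect_equal(predict(fit3, tbl[tbl$id == "BZL", ]), -8.89, tolerance = 1e-8)
})

test_that("the exact solve agrees with an independent least-squares route", {
  tbl <- benzil_table("qsar")
  fit <- qsar_fit(tbl, "be_3WMT")
  lm_fit <- stats::lm(be_3WMT ~ ip + ea + s + omega, data = tbl)
  expect_equal(unname(fit$coefficients[c("ip", "ea", "s", "omega")]),
               unname(stats::coef(lm_fit)[c("ip", "ea", "s", "omega")]),
               tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["intercept"]),
               unname(stats::coef(lm_fit)["(Intercept)"]), tolerance = 1e-6)
})

test_that("overdetermined fits leave residuals orthogonal to the design", {
  set.seed(51)
  n <- 12
  data <- tibble::tibble(
    ip = runif(n, 8, 9), ea = runif(n, 5.5, 6.2),
    s = runif(n, 0.6, 0.9), omega = runif(n, 17, 21)
  )
  data$y <- -100 * data$ip + 50 * data$ea - 400 * data$s + 5 * data$omega +
    700 + rnorm(n, 0, 0.3)
  fit <- qsar_fit(data, "y")
  expect_false(fit$exact_fit)
  X <- cbind(as.matrix(data[c("ip", "ea", "s", "omega")]), 1)
  expect_lt(max(abs(crossprod(X, fit$residuals))) / max(abs(data$y)), 1e-10)

  # consistent responses reduce least squares to an exact fit
  data$y0 <- -2 * data$ip + 3 * data$s + 1
  fit0 <- qsar_fit(data, "y0")
  expect_lt(max(abs(fit0$residuals)), 1e-9)
})

test_that("rank-deficient square designs raise a singularity error", {
  tbl <- benzil_table("qsar")
  dup <- dplyr::bind_rows(tbl[1:4, ], tbl[1, ])
  expect_error(qsar_fit(dup, "be_3WMT"), class = "benzilkit_error_singular")
  expect_error(qsar_fit(tbl[1:3, ], "be_3WMT"), class = "benzilkit_error_input")
})

test_that("prediction with zero descriptors returns the intercept", {
  fit <- qsar_fit(benzil_table("qsar"), "be_3WMT")
  zero <- tibble::tibble(ip = 0, ea = 0, s = 0, omega = 0)
  expect_equal(predict(fit, zero), unname(fit$coefficients["intercept"]))
})

test_that("sign comparison reports agreement without pass/fail semantics", {
  fit <- qsar_fit(benzil_table("qsar"), "be_3WMT")
  same <- compare_signs(fit, fit$coefficients)
  expect_true(all(same$agree))
  flipped <- compare_signs(fit, -fit$coefficients)
  expect_false(any(flipped$agree))
  expect_error(compare_signs(fit, c(ip = 1)), class = "benzilkit_error_input")
})

test_that("published integer coefficients do not reproduce the binding energies", {
  # integer rounding destroys the exact interpolation; the report quantifies
  # the discrepancy instead of asserting agreement
  rep3 <- qsar_printed_report("3WMT")
  expect_equal(nrow(rep3$signs), 5)
  printed <- c(ip = -101, ea = 53, s = -493, omega = 6, intercept = 784)
  bzl <- benzil_table("qsar")[1, ]
  oracle <- sum(printed[c("ip", "ea", "s", "omega")] *
                  c(bzl$ip, bzl$ea, bzl$s, bzl$omega)) + printed["intercept"]
  row <- rep3$printed_prediction[rep3$printed_prediction$id == "BZL", ]
  expect_equal(row$be_printed_coefs, unname(oracle), tolerance = 1e-9)
  expect_equal(row$discrepancy, unname(oracle) - (-8.89), tolerance = 1e-9)
  expect_gt(abs(row$discrepancy), 1)
})

test_that("tidy, glance and autoplot expose the fitted model", {
  fit <- qsar_fit(benzil_table("qsar"), "be_2EEP", receptor = "2EEP")
  td <- tidy(fit)
  expect_equal(td$term, c("ip", "ea", "s", "omega", "intercept"))
  gl <- glance(fit)
  expect_equal(gl$receptor, "2EEP")
  expect_true(gl$exact_fit)
  expect_lt(gl$max_abs_residual, 1e-8)
  expect_s3_class(autoplot(fit), "ggplot")
})
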