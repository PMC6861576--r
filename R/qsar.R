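#' Linear QSAR model of binding energy on reactivity descriptors
#'
#' Fits binding energy as a linear function of conceptual-DFT descriptors
#' (by default IP, EA, softness S and electrophilicity index omega, plus an
#' intercept). When the system is square (n observations = p predictors +
#' 1) and nonsingular it is solved exactly, so the fit interpolates the
#' training responses; overdetermined systems are solved by least squares.
#' The derived descriptors chi, mu and eta are deliberately excluded from
#' the default design: they are linear combinations of IP and EA and would
#' make the square design singular.
#'
#' @param data Data frame holding the descriptor columns and the response.
#' @param response Name of the response column (string), e.g. a binding
#'   energy from [binding_energy_vector()].
#' @param predictors Character vector of descriptor column names (default
#'   `c("ip", "ea", "s", "omega")`).
#' @param receptor Optional receptor label carried into the model object.
#' @param id Name of an id column to record as the design ids (default
#'   `"id"` when present).
#' @return An object of class `qsar_fit`: coefficients (predictors then
#'   `intercept`), fitted values, residuals, condition number of the design,
#'   and an `exact_fit` flag (square and nonsingular). A warning is issued
#'   when the design's condition number exceeds 1e8.
#' @examples
#' tbl <- benzil_table("qsar")
#' fit <- qsar_fit(tbl, response = "be_3WMT", receptor = "3WMT")
#' tidy(fit)
#' glance(fit)
#' @export
qsar_fit <- function(data, response, predictors = c("ip", "ea", "s", "omega"),
                     receptor = NULL, id = "id") {
  check_columns(data, c(predictors, response))
  n <- nrow(data)
  p <- length(predictors)
  if (n < p + 1) {
    abort(sprintf("Need at least %d rows to fit %d predictors plus intercept; got %d.",
                  p + 1, p, n),
          class = "benzilkit_error_input")
  }
  X <- cbind(as.matrix(data[predictors]), intercept = 1)
  y <- as.numeric(data[[response]])
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[seq(qr_x$rank + 1, ncol(X))]]
    abort(sprintf("Singular design: collinear column(s) %s.",
                  paste(bad, collapse = ", ")),
          class = "benzilkit_error_singular")
  }
  coef <- qr.coef(qr_x, y)
  fitted <- drop(X %*% coef)
  kappa_x <- kappa(X, exact = TRUE)
  if (kappa_x > 1e8) {
    warn(sprintf("Ill-conditioned design (condition number %.3g).", kappa_x))
  }
  structure(
    list(
      coefficients = coef,
      predictors = predictors,
      response = response,
      receptor = receptor,
      design_ids = if (id %in% names(data)) as.character(data[[id]]) else NULL,
      condition_number = kappa_x,
      exact_fit = n == p + 1,
      fitted = fitted,
      residuals = y - fitted,
      y = y
    ),
    class = "qsar_fit"
  )
}

#' @export
print.qsar_fit <- function(x, ...) {
  cat("QSAR linear model", if (!is.null(x$receptor)) sprintf("(receptor %s)", x$receptor), "\n")
  cat(sprintf("  %s ~ %s + intercept\n", x$response, paste(x$predictors, collapse = " + ")))
  cat(sprintf("  n = %d, %s, condition number %.3g\n",
              length(x$y), if (x$exact_fit) "exact (square) solve" else "least squares",
              x$condition_number))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict binding energy from a fitted QSAR model
#'
#' @param object A `qsar_fit`.
#' @param newdata Data frame with the model's predictor columns.
#' @param ... Unused.
#' @return Numeric vector of predicted binding energies.
#' @examples
#' tbl <- benzil_table("qsar")
#' fit <- qsar_fit(tbl, "be_3WMT")
#' predict(fit, tbl)
#' @export
predict.qsar_fit <- function(object, newdata, ...) {
  check_columns(newdata, object$predictors, arg = "newdata")
  X <- cbind(as.matrix(newdata[object$predictors]), intercept = 1)
  drop(X %*% object$coefficients)
}

#' @describeIn qsar_fit Broom-style coefficient table.
#' @param x A `qsar_fit`.
#' @param ... Unused.
#' @export
tidy.qsar_fit <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @describeIn qsar_fit Broom-style one-row model summary.
#' @export
glance.qsar_fit <- function(x, ...) {
  tibble(
    receptor = if (is.null(x$receptor)) NA_character_ else x$receptor,
    n = length(x$y),
    exact_fit = x$exact_fit,
    condition_number = x$condition_number,
    max_abs_residual = max(abs(x$residuals))
  )
}

#' Compare fitted coefficient signs against a published set
#'
#' Reports, per coefficient, the fitted sign versus a published sign. There
#' are no pass/fail semantics: published coefficients are often rounded
#' aggressively (integers), which destroys an exact interpolation, so the
#' comparison is descriptive. Use [qsar_printed_report()] for the packaged
#' published set.
#'
#' @param model A `qsar_fit`.
#' @param printed Named numeric vector with one value per model term
#'   (predictors plus `intercept`).
#' @return A tibble with `term`, `fitted`, `printed`, `fitted_sign`,
#'   `printed_sign`, `agree`.
#' @examples
#' fit <- qsar_fit(benzil_table("qsar"), "be_3WMT")
#' compare_signs(fit, c(ip = -101, ea = 53, s = -493, omega = 6, intercept = 784))
#' @export
compare_signs <- function(model, printed) {
  terms <- names(model$coefficients)
  if (is.null(names(printed)) || !setequal(names(printed), terms)) {
    abort(sprintf("`printed` must be a complete named tuple over terms: %s.",
                  paste(terms, collapse = ", ")),
          class = "benzilkit_error_input")
  }
  printed <- printed[terms]
  tibble(
    term = terms,
    fitted = unname(model$coefficients),
    printed = unname(printed),
    fitted_sign = sign(unname(model$coefficients)),
    printed_sign = sign(unname(printed)),
    agree = sign(unname(model$coefficients)) == sign(unname(printed))
  )
}

#' Refit-vs-published QSAR report for one receptor
#'
#' Refits the saturated model on the packaged descriptor/binding-energy
#' table, then reports the sign agreement with the published integer
#' coefficients and the discrepancy between published-coefficient
#' predictions and the actual binding energies. The published integers are
#' never used as the model of record: applied directly to the descriptor
#' rows they do not reproduce the binding-energy column (integer rounding
#' breaks the exact interpolation), and this report quantifies rather than
#' asserts that discrepancy.
#'
#' @param receptor `"3WMT"`, `"2H4Z"` or `"2EEP"`.
#' @return A list with elements `fit` (the `qsar_fit`), `signs` (the
#'   [compare_signs()] tibble) and `printed_prediction` (tibble with
#'   per-molecule observed BE, published-coefficient prediction and the
#'   discrepancy).
#' @examples
#' rep <- qsar_printed_report("3WMT")
#' rep$signs
#' @export
qsar_printed_report <- function(receptor = c("3WMT", "2H4Z", "2EEP")) {
  receptor <- match.arg(receptor)
  tbl <- benzil_table("qsar")
  response <- paste0("be_", receptor)
  fit <- qsar_fit(tbl, response = response, receptor = receptor)
  printed_tbl <- filter(benzil_table("printed_coefficients"), .data$receptor == !!receptor)
  printed <- c(ip = printed_tbl$b_ip, ea = printed_tbl$b_ea, s = printed_tbl$b_s,
               omega = printed_tbl$b_omega, intercept = printed_tbl$intercept)
  X <- cbind(as.matrix(tbl[fit$predictors]), intercept = 1)
  printed_pred <- drop(X %*% printed)
  list(
    fit = fit,
    signs = compare_signs(fit, printed),
    printed_prediction = tibble(
      id = tbl$id,
      be_observed = tbl[[response]],
      be_printed_coefs = printed_pred,
      discrepancy = printed_pred - tbl[[response]]
    )
  )
}
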