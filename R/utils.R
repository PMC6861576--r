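#' Round half away from zero
#'
#' Commercial rounding: exact halves move away from zero, unlike [round()]'s
#' round-half-even. Used for fold-ratios against a reference material, where
#' "x times urea" is conventionally a commercially rounded integer.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded to `digits` places.
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5, 14.82))
#' @export
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  # tiny epsilon so decimal halves stored just below .5 in binary still go up
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# shared input check: x must be a data frame containing the given columns
check_columns <- function(data, cols, arg = "data") {
  if (!is.data.frame(data)) {
    abort(sprintf("`%s` must be a data frame.", arg), class = "benzilkit_error_input")
  }
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(
      sprintf("`%s` is missing required column(s): %s.", arg, paste(missing, collapse = ", ")),
      class = "benzilkit_error_input"
    )
  }
  invisible(data)
}

check_unique_ids <- function(id) {
  dup <- unique(id[duplicated(id)])
  if (length(dup) > 0) {
    abort(
      sprintf("Duplicate id(s): %s.", paste(dup, collapse = ", ")),
      class = "benzilkit_error_input"
    )
  }
  invisible(id)
}

#' Path to a packaged fixture file
#'
#' @param file File name under the package's `extdata/` directory.
#' @return Absolute path to the installed fixture.
#' @keywords internal
benzilkit_extdata <- function(file) {
  path <- system.file("extdata", file, package = "benzilkit")
  if (identical(path, "")) {
    abort(sprintf("Packaged fixture '%s' not found.", file), class = "benzilkit_error_io")
  }
  path
}
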