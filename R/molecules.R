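#' Read molecule electronic-structure summaries from JSON
#'
#' Parses a JSON file of per-molecule electronic-structure summaries
#' (frontier orbital energies, vertical IP/EA, excitation records, dipole and
#' NLO scalars) into a tibble, validating every record against the schema
#' documented in `inst/extdata/SCHEMA.md`. Violations are reported with the
#' offending molecule and field named.
#'
#' The vertical ionisation potential and electron affinity are stored
#' independently of the orbital energies: conceptual-DFT tables in the
#' literature are frequently *not* derivable from the corresponding
#' orbital-energy tables (Koopmans-style IP = -E(HOMO) rarely matches a
#' printed vertical IP), so the schema never derives one from the other.
#'
#' @param path Path to a JSON file with a top-level `molecules` array.
#' @return A tibble with one row per molecule: `id`, `name`, `e_homo`,
#'   `e_lumo`, `ip_vertical`, `ea_vertical`, `dipole_debye`, `method_note`,
#'   plus list-columns `excitations` (tibbles with `lambda_nm`, `f`,
#'   `composition`) and `nlo` (named lists of scalar and/or tensor blocks).
#' @examples
#' mols <- benzil_molecules()
#' mols$id
#' @seealso [benzil_molecules()] for the packaged benzil-series fixture.
#' @export
read_molecule_summaries <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File '%s' does not exist.", path), class = "benzilkit_error_io")
  }
  parsed <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) {
      abort(
        sprintf("File '%s' is not valid JSON: %s", path, conditionMessage(e)),
        class = "benzilkit_error_schema"
      )
    }
  )
  records <- parsed[["molecules"]]
  if (is.null(records) || length(records) == 0) {
    abort(
      sprintf("File '%s' contains no `molecules` array.", path),
      class = "benzilkit_error_schema"
    )
  }
  out <- purrr::map(records, parse_molecule_record)
  tbl <- dplyr::bind_rows(out)
  check_unique_ids(tbl$id)
  tbl
}

parse_molecule_record <- function(rec) {
  mandatory <- c("id", "e_homo", "e_lumo")
  for (field in mandatory) {
    if (is.null(rec[[field]])) {
      abort(
        sprintf(
          "Molecule record %s is missing mandatory field `%s`.",
          if (is.null(rec$id)) "(no id)" else sprintf("'%s'", rec$id), field
        ),
        class = "benzilkit_error_schema"
      )
    }
  }
  id <- as.character(rec$id)
  e_homo <- as.numeric(rec$e_homo)
  e_lumo <- as.numeric(rec$e_lumo)
  if (!is.finite(e_homo) || !is.finite(e_lumo) || e_homo >= e_lumo) {
    abort(
      sprintf("Molecule '%s': invariant e_homo < e_lumo violated (%s vs %s).", id, e_homo, e_lumo),
      class = "benzilkit_error_validation"
    )
  }
  ip <- if (is.null(rec$ip_vertical)) NA_real_ else as.numeric(rec$ip_vertical)
  ea <- if (is.null(rec$ea_vertical)) NA_real_ else as.numeric(rec$ea_vertical)
  if (!is.na(ip) && !is.na(ea) && ip <= ea) {
    abort(
      sprintf("Molecule '%s': invariant ip_vertical > ea_vertical violated.", id),
      class = "benzilkit_error_validation"
    )
  }
  exc <- parse_excitations(rec$excitations, id)
  tibble(
    id = id,
    name = if (is.null(rec$name)) NA_character_ else as.character(rec$name),
    e_homo = e_homo,
    e_lumo = e_lumo,
    ip_vertical = ip,
    ea_vertical = ea,
    dipole_debye = if (is.null(rec$dipole_debye)) NA_real_ else as.numeric(rec$dipole_debye),
    excitations = list(exc),
    nlo = list(rec$nlo),
    method_note = if (is.null(rec$method_note)) NA_character_ else as.character(rec$method_note)
  )
}

parse_excitations <- function(excitations, id) {
  if (is.null(excitations) || length(excitations) == 0) {
    return(tibble(lambda_nm = numeric(), f = numeric(), composition = list()))
  }
  rows <- purrr::map(excitations, function(e) {
    lambda <- as.numeric(e$lambda_nm)
    f <- as.numeric(e$f)
    if (!is.finite(lambda) || lambda <= 0) {
      abort(sprintf("Molecule '%s': excitation wavelength must be > 0.", id),
            class = "benzilkit_error_validation")
    }
    if (!is.finite(f) || f < 0) {
      abort(sprintf("Molecule '%s': oscillator strength must be >= 0.", id),
            class = "benzilkit_error_validation")
    }
    comp <- purrr::map(e$composition %||% list(), function(cc) {
      tibble(
        donor = as.character(cc$donor),
        acceptor = as.character(cc$acceptor),
        weight = as.numeric(cc$weight)
      )
    }) %>% dplyr::bind_rows()
    if (nrow(comp) > 0) {
      if (any(comp$weight <= 0 | comp$weight > 100)) {
        abort(sprintf("Molecule '%s': composition weights must lie in (0, 100].", id),
              class = "benzilkit_error_validation")
      }
      if (sum(comp$weight) > 100 + 1e-9) {
        abort(sprintf("Molecule '%s': composition weights sum above 100%%.", id),
              class = "benzilkit_error_validation")
      }
    }
    tibble(lambda_nm = lambda, f = f, composition = list(comp))
  })
  dplyr::bind_rows(rows)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Packaged benzil-series molecule summaries
#'
#' The five dyes of the study series: benzil (BZL) and its para-substituted
#' dimethyl (DMB), difluoro (DFB), dichloro (DCB) and dibromo (DBB)
#' analogues, with orbital energies, vertical IP/EA, the dominant
#' TD-DFT excitation and NLO scalars as published.
#'
#' @return A molecule-summary tibble (see [read_molecule_summaries()]).
#' @examples
#' benzil_molecules()
#' @export
benzil_molecules <- function() {
  read_molecule_summaries(benzilkit_extdata("benzil_series.json"))
}

#' Packaged study tables
#'
#' Accessor for the plain-text transcriptions of the study's flat tables
#' shipped with the package.
#'
#' @param name One of `"photovoltaics"` (printed photovoltaic table),
#'   `"descriptors"` (printed reactivity descriptors), `"nlo"` (NLO
#'   scalars), `"docking"` (ranked docking scores), `"qsar"` (descriptors
#'   plus binding energies), `"printed_coefficients"` (the published integer
#'   regression coefficients) or `"torsion_metadata"` (printed barriers and
#'   extrema angles).
#' @return A tibble.
#' @examples
#' benzil_table("descriptors")
#' @export
benzil_table <- function(name = c("photovoltaics", "descriptors", "nlo", "docking",
                                  "qsar", "printed_coefficients", "torsion_metadata")) {
  name <- match.arg(name)
  file <- switch(name,
    photovoltaics = "table1_photovoltaics.csv",
    descriptors = "table2_descriptors.csv",
    nlo = "table3_nlo.csv",
    docking = "table4_docking.csv",
    qsar = "table5_qsar.csv",
    printed_coefficients = "qsar_printed_coefficients.csv",
    torsion_metadata = "torsion_metadata.csv"
  )
  readr::read_csv(benzilkit_extdata(file), comment = "#", show_col_types = FALSE)
}

#' Packaged vibrational assignment table for one molecule
#'
#' Row-wise calculated/observed vibrational assignments as published:
#' scaled calculated wavenumbers with IR intensities and Raman activities,
#' alongside the observed IR and (where reported) Raman bands.
#'
#' @param id Molecule label: `"BZL"`, `"DMB"`, `"DFB"`, `"DCB"` or `"DBB"`.
#' @return A tibble with columns `calc`, `ir_int`, `raman_act`, `obs_ir`,
#'   `obs_raman`, `assignment`. Missing observed bands are `NA`.
#' @examples
#' benzil_vibrations("BZL")
#' @export
benzil_vibrations <- function(id = c("BZL", "DMB", "DFB", "DCB", "DBB")) {
  id <- match.arg(id)
  readr::read_csv(benzilkit_extdata(paste0("vib_", id, ".csv")),
                  comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    calc = "d", ir_int = "d", raman_act = "d",
                    obs_ir = "d", obs_raman = "d", assignment = "c"
                  ))
}

#' Write a derived table to CSV or markdown
#'
#' CSV output is round-trip safe: reading the written file back reproduces
#' the stored values to full double precision.
#'
#' @param data A non-empty data frame with homogeneous columns.
#' @param path Output file path.
#' @param format `"csv"` or `"markdown"`.
#' @return `data`, invisibly.
#' @examples
#' \donttest{
#' tmp <- tempfile(fileext = ".csv")
#' write_report_table(benzil_table("descriptors"), tmp)
#' }
#' @export
write_report_table <- function(data, path, format = c("csv", "markdown")) {
  format <- match.arg(format)
  if (!is.data.frame(data) || nrow(data) == 0) {
    abort("`data` must be a non-empty data frame.", class = "benzilkit_error_input")
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort(sprintf("Cannot write to '%s': directory does not exist.", path),
          class = "benzilkit_error_io")
  }
  if (format == "csv") {
    readr::write_csv(data, path)
  } else {
    writeLines(markdown_table(data), path)
  }
  invisible(data)
}

# minimal pipe-table formatter; numbers printed with up to 15 significant digits
markdown_table <- function(data) {
  cells <- purrr::map(data, function(col) {
    if (is.numeric(col)) format(col, digits = 15, trim = TRUE, scientific = FALSE) else as.character(col)
  })
  cells <- purrr::map(cells, function(x) ifelse(is.na(x) | x == "NA", "", x))
  widths <- purrr::map2_int(names(data), cells, ~ max(nchar(c(.x, .y)), 3L))
  pad <- function(x, w) formatC(x, width = w, flag = "-")
  header <- paste0("| ", paste(purrr::map2_chr(names(data), widths, pad), collapse = " | "), " |")
  rule <- paste0("|", paste(purrr::map_chr(widths, ~ strrep("-", .x + 2)), collapse = "|"), "|")
  body <- purrr::map_chr(seq_len(nrow(data)), function(i) {
    row <- purrr::map_chr(cells, ~ .x[[i]])
    paste0("| ", paste(purrr::map2_chr(row, widths, pad), collapse = " | "), " |")
  })
  c(header, rule, body)
}
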