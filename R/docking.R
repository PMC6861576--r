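#' Read and validate a ranked docking score table
#'
#' Reads a long-format CSV of docking scores (columns `receptor, ligand,
#' rank, global_energy, attractive_vdw, repulsive_vdw, ace`) and validates
#' every receptor-ligand block: ranks must run 1..n without gaps, repulsive
#' van der Waals terms must be nonnegative, and the rank-1 conformation
#' must carry the block's minimum (most negative) global energy, i.e. the
#' table is sorted the way geometric docking servers emit it. Violations
#' are reported with the offending block named. Score units are opaque.
#'
#' @param path CSV path (the packaged fixture via [benzil_docking()]).
#' @return A validated tibble.
#' @export
read_docking_scores <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File '%s' does not exist.", path), class = "benzilkit_error_io")
  }
  data <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if (nrow(data) == 0) {
    return(tibble(receptor = character(), ligand = character(), rank = integer(),
                  global_energy = numeric(), attractive_vdw = numeric(),
                  repulsive_vdw = numeric(), ace = numeric()))
  }
  check_columns(data, c("receptor", "ligand", "rank", "global_energy",
                        "attractive_vdw", "repulsive_vdw", "ace"))
  validate_docking_blocks(data)
  as_tibble(data)
}

validate_docking_blocks <- function(data) {
  blocks <- split(data, paste(data$receptor, data$ligand, sep = "-"))
  for (label in names(blocks)) {
    block <- blocks[[label]]
    if (!identical(sort(as.integer(block$rank)), seq_len(nrow(block)))) {
      abort(sprintf("Block %s: ranks must run 1..n without gaps.", label),
            class = "benzilkit_error_validation")
    }
    block <- block[order(block$rank), ]
    if (any(block$repulsive_vdw < 0)) {
      abort(sprintf("Block %s: repulsive vdW terms must be >= 0.", label),
            class = "benzilkit_error_validation")
    }
    if (block$global_energy[1] > min(block$global_energy)) {
      abort(sprintf("Block %s: rank 1 must have the minimum global energy.", label),
            class = "benzilkit_error_validation")
    }
  }
  invisible(data)
}

#' Packaged docking score table
#'
#' The study's top-10 docking conformations for every receptor-ligand
#' complex: three receptors (3WMT feruloyl esterase, 2H4Z
#' bisphosphoglycerate mutase, 2EEP prolyl aminopeptidase) times the five
#' benzil-series ligands.
#'
#' @return A validated docking tibble (150 rows).
#' @examples
#' benzil_docking() |> dplyr::count(receptor, ligand)
#' @export
benzil_docking <- function() {
  read_docking_scores(benzilkit_extdata("table4_docking.csv"))
}

#' Top-ranked conformation per complex
#'
#' @param data Docking tibble (any number of receptor-ligand blocks).
#' @return The rank-1 row(s), one per block.
#' @examples
#' benzil_docking() |> dplyr::filter(receptor == "3WMT") |> top_conformation()
#' @export
top_conformation <- function(data) {
  check_columns(data, c("receptor", "ligand", "rank"))
  if (nrow(data) == 0) {
    abort("Docking table is empty.", class = "benzilkit_error_input")
  }
  filter(data, .data$rank == 1L)
}

#' Best ligand for one receptor by a docking metric
#'
#' Picks the ligand whose chosen statistic of the chosen metric is most
#' negative (stabilizing); ties break by ligand id. `statistic = "rank1"`
#' looks only at each block's top conformation, `"min"` at the block
#' minimum across all conformations.
#'
#' @param data Docking tibble, all rows from the same receptor.
#' @param metric `"global_energy"` or `"ace"` (atomic contact energy).
#' @param statistic `"rank1"` or `"min"`.
#' @return One-row tibble with `ligand` and `value`.
#' @examples
#' benzil_docking() |> dplyr::filter(receptor == "3WMT") |> best_complex()
#' @export
best_complex <- function(data, metric = c("global_energy", "ace"),
                         statistic = c("rank1", "min")) {
  metric <- match.arg(metric)
  statistic <- match.arg(statistic)
  check_columns(data, c("receptor", "ligand", "rank", metric))
  if (nrow(data) == 0) {
    abort("Docking table is empty.", class = "benzilkit_error_input")
  }
  if (length(unique(data$receptor)) > 1) {
    abort("All rows must come from the same receptor (mixed receptors supplied).",
          class = "benzilkit_error_input")
  }
  per_ligand <- data %>%
    group_by(.data$ligand) %>%
    summarise(value = if (statistic == "rank1") {
      .data[[metric]][.data$rank == 1L][1]
    } else {
      min(.data[[metric]])
    }, .groups = "drop") %>%
    arrange(.data$value, .data$ligand)
  per_ligand[1, ]
}

#' Binding-energy vector for a receptor
#'
#' The rank-1 atomic contact energy of each ligand against one receptor.
#' This is the response vector of the QSAR model: the study's binding
#' energies coincide cell-for-cell with the top-conformation ACE of the
#' docking table, so the pipeline builds them from the score table rather
#' than duplicating numbers.
#'
#' @param data Docking tibble (may hold several receptors).
#' @param receptor Receptor id to extract.
#' @param ligands Ligands that must all be present (default the five study
#'   dyes).
#' @return A tibble with `ligand` and `be` (rank-1 ACE, score units), in
#'   `ligands` order.
#' @examples
#' binding_energy_vector(benzil_docking(), "3WMT")
#' @export
binding_energy_vector <- function(data, receptor,
                                  ligands = c("BZL", "DMB", "DFB", "DCB", "DBB")) {
  check_columns(data, c("receptor", "ligand", "rank", "ace"))
  sub <- filter(data, .data$receptor == !!receptor, .data$rank == 1L)
  missing <- setdiff(ligands, sub$ligand)
  if (length(missing) > 0) {
    abort(sprintf("Receptor %s: missing ligand block(s): %s.",
                  receptor, paste(missing, collapse = ", ")),
          class = "benzilkit_error_input")
  }
  tibble(ligand = ligands) %>%
    left_join(select(sub, "ligand", be = "ace"), by = "ligand")
}
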