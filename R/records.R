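#' Construct an interaction record table
#'
#' The canonical tabular container used throughout the package: one row per
#' (protein, molecule) pair with a binary label and a provenance flag saying
#' whether the pair was measured or generated by network-based negative
#' sampling. Binding records are always measured.
#'
#' @param protein_id,molecule_id character vectors
#' @param label "binding" or "nonbinding"
#' @param provenance "measured" or "network_negative"
#' @param affinity_nM,affinity_type optional affinity annotation
#' @return tibble of interaction records
#' @export
interaction_records <- function(protein_id, molecule_id, label,
                                provenance = "measured",
                                affinity_nM = NA_real_,
                                affinity_type = NA_character_) {
  rec <- tibble::tibble(
    protein_id = as.character(protein_id),
    molecule_id = as.character(molecule_id),
    label = as.character(label),
    provenance = provenance,
    affinity_nM = affinity_nM,
    affinity_type = affinity_type
  )
  bad <- !rec$label %in% c("binding", "nonbinding")
  if (any(bad)) stop_validation("labels must be 'binding' or 'nonbinding'")
  if (any(rec$label == "binding" & rec$provenance != "measured")) {
    stop_validation("binding records must have provenance 'measured'")
  }
  rec
}

#' Read an interaction table from a delimited file
#'
#' Accepts either (protein_id, molecule_id, affinity_nM, affinity_type) — in
#' which case labels come from [label_from_affinity()] and records in the
#' excluded band are dropped — or (protein_id, molecule_id, label).
#'
#' @param path a TSV/CSV file with a header
#' @param sep field separator (default tab)
#' @return tibble of interaction records
#' @export
read_interactions <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (all(c("affinity_nM", "affinity_type") %in% names(df))) {
    lab <- label_from_affinity(df$affinity_nM)
    keep <- lab != "excluded"
    interaction_records(
      df$protein_id[keep], df$molecule_id[keep], lab[keep],
      affinity_nM = df$affinity_nM[keep], affinity_type = df$affinity_type[keep]
    )
  } else if ("label" %in% names(df)) {
    interaction_records(df$protein_id, df$molecule_id, df$label)
  } else {
    stop_parse("interaction table needs either affinity columns or a label column")
  }
}

#' Read a two-column molecule table (molecule_id, smiles)
#' @param path delimited file with header
#' @param sep field separator
#' @return named character vector of SMILES keyed by molecule id
#' @export
read_molecules <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("molecule_id", "smiles") %in% names(df))) {
    stop_parse("molecule table must have columns molecule_id, smiles")
  }
  setNames(df$smiles, df$molecule_id)
}

#' Per-protein positive ratio of an interaction table
#' @param records interaction record tibble
#' @return tibble (protein_id, n, n_binding, positive_ratio)
#' @export
positive_ratio <- function(records) {
  records |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_binding = sum(.data$label == "binding"),
      positive_ratio = .data$n_binding / .data$n,
      .groups = "drop"
    )
}

#' @importFrom rlang .data
NULL
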