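#' Extract a hard pocket prediction from a soft assignment matrix
#'
#' Residue i belongs to the predicted pocket iff its pocket-membership
#' probability `Z[i, 1]` is at least `threshold` (inclusive).
#'
#' @param Z n x 2 row-stochastic assignment matrix
#' @param threshold inclusion threshold (default 0.5)
#' @param protein_id,source metadata carried on the prediction
#' @return object of class `pocket_prediction` with 0-based
#'   `residue_indices`
#' @export
extract_pocket <- function(Z, threshold = 0.5, protein_id = NA_character_,
                           source = "sib") {
  idx <- which(Z[, 1L] >= threshold) - 1L
  structure(
    list(protein_id = protein_id, residue_indices = idx, source = source,
         n_residues = nrow(Z)),
    class = "pocket_prediction"
  )
}

#' Uniformly random pocket of a given size (the random baseline)
#'
#' @param n_residues protein size
#' @param size pocket size (typically the true pocket size)
#' @param protein_id metadata
#' @return a `pocket_prediction` with source "random_baseline"
#' @export
random_pocket <- function(n_residues, size, protein_id = NA_character_) {
  idx <- sort(sample.int(n_residues, min(size, n_residues))) - 1L
  structure(
    list(protein_id = protein_id, residue_indices = idx,
         source = "random_baseline", n_residues = n_residues),
    class = "pocket_prediction"
  )
}

as_index_set <- function(x) {
  if (inherits(x, "pocket_prediction")) x$residue_indices else as.integer(x)
}

#' Jaccard similarity coefficient of two residue index sets
#'
#' \eqn{|A \cap B| / |A \cup B|}; defined as 0 when both sets are empty.
#'
#' @param pred,truth integer index sets (or `pocket_prediction`s)
#' @return value in [0, 1]
#' @export
jaccard <- function(pred, truth) {
  a <- unique(as_index_set(pred))
  b <- unique(as_index_set(truth))
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' First-order neighbors of a residue set on the contact graph
#' @param indices 0-based residue indices
#' @param graph a `protein_graph`
#' @return 0-based indices of the set plus its contact neighbors
#' @export
neighbor_expand <- function(indices, graph) {
  idx <- as_index_set(indices)
  if (any(idx < 0L | idx >= graph$n_residues)) {
    stop_validation("residue index out of range")
  }
  if (length(idx) == 0L) return(integer(0))
  nbr <- which(rowSums(graph$adjacency[, idx + 1L, drop = FALSE]) > 0) - 1L
  sort(union(idx, nbr))
}

#' Jaccard against the neighbor-expanded true pocket
#'
#' `jaccard(pred, truth ∪ neighbors(truth))` with first-order neighbors taken
#' from the residue contact graph; credits predictions that land adjacent to
#' the true pocket.
#'
#' @param pred predicted residue indices
#' @param truth true pocket indices
#' @param graph a `protein_graph`
#' @return value in [0, 1]
#' @export
neighbor_jaccard <- function(pred, truth, graph) {
  jaccard(pred, neighbor_expand(truth, graph))
}

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney statistic with mid-ranks for ties.
#'
#' @param labels 0/1 (or logical, or "binding"/"nonbinding") labels
#' @param scores numeric scores, larger = more positive
#' @return AUROC in [0, 1]
#' @export
auroc <- function(labels, scores) {
  y <- normalize_labels(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) {
    stop_validation("AUROC undefined: both classes must be present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-interpolated integration of precision over recall at every distinct
#' score threshold (average-precision form).
#'
#' @inheritParams auroc
#' @return AUPRC in (0, 1]
#' @export
auprc <- function(labels, scores) {
  y <- normalize_labels(labels)
  if (!any(y == 1) || !any(y == 0)) {
    stop_validation("AUPRC undefined: both classes must be present")
  }
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]
  s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  keep <- c(s[-1] != s[-length(s)], TRUE)   # one operating point per threshold
  tp <- tp[keep]
  fp <- fp[keep]
  precision <- tp / (tp + fp)
  recall <- tp / sum(y)
  sum(diff(c(0, recall)) * precision)
}

normalize_labels <- function(labels) {
  if (is.character(labels)) return(as.numeric(labels == "binding"))
  as.numeric(labels)
}

#' Per-protein classification report
#'
#' AUROC/AUPRC per protein; proteins lacking either class are excluded.
#'
#' @param predictions tibble with columns protein_id, label, score
#' @return tibble (protein_id, n_pos, n_neg, auroc, auprc)
#' @export
per_protein_report <- function(predictions) {
  predictions |>
    dplyr::mutate(y = normalize_labels(.data$label)) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      n_pos = sum(.data$y == 1), n_neg = sum(.data$y == 0),
      auroc = if (n_pos[1] > 0 && n_neg[1] > 0) auroc(.data$y, .data$score)
              else NA_real_,
      auprc = if (n_pos[1] > 0 && n_neg[1] > 0) auprc(.data$y, .data$score)
              else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_pos > 0, .data$n_neg > 0)
}
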