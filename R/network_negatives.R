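#' Build the bipartite drug-target network from measured records
#'
#' Nodes are proteins and molecules; an edge joins a protein and a molecule
#' whenever a measured record (of either label) links them. Used by the
#' network-based negative sampling augmentation.
#'
#' @param records interaction record tibble (measured records; any
#'   network-generated rows are ignored)
#' @return object of class `dti_network` wrapping an igraph graph plus the
#'   protein/molecule node id sets and the measured edge set
#' @export
build_network <- function(records) {
  if (nrow(records) == 0L) stop_validation("records must be non-empty")
  meas <- records[records$provenance == "measured", , drop = FALSE]
  proteins <- unique(meas$protein_id)
  molecules <- unique(meas$molecule_id)
  if (length(intersect(proteins, molecules))) {
    stop_validation("protein and molecule id sets must be disjoint")
  }
  pairs <- unique(paste(meas$protein_id, meas$molecule_id, sep = "\r"))
  sp <- strsplit(pairs, "\r", fixed = TRUE)
  edge_p <- vapply(sp, `[`, "", 1L)
  edge_m <- vapply(sp, `[`, "", 2L)
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(c(proteins, molecules),
                     type = rep(c(TRUE, FALSE), c(length(proteins), length(molecules))))
  g <- igraph::add_edges(g, rbind(match(edge_p, c(proteins, molecules)),
                                  match(edge_m, c(proteins, molecules))))
  structure(
    list(graph = g, proteins = proteins, molecules = molecules,
         edges = tibble::tibble(protein_id = edge_p, molecule_id = edge_m)),
    class = "dti_network"
  )
}

#' @export
print.dti_network <- function(x, ...) {
  cat(sprintf("<dti_network: %d proteins, %d molecules, %d edges>\n",
              length(x$proteins), length(x$molecules), nrow(x$edges)))
  invisible(x)
}

#' Shortest-path hop distance between a protein and a molecule
#'
#' Unweighted shortest path on the bipartite network (breadth-first search;
#' identical to Dijkstra on unit edge weights). `Inf` when the two nodes lie
#' in different components. Bipartiteness makes every finite
#' protein-molecule distance odd.
#'
#' @param network a `dti_network`
#' @param protein_id,molecule_id node ids
#' @return integer hop count or `Inf`
#' @export
shortest_distance <- function(network, protein_id, molecule_id) {
  ids <- igraph::V(network$graph)$name
  if (!protein_id %in% network$proteins) {
    stop_lookup(sprintf("unknown protein id '%s'", protein_id))
  }
  if (!molecule_id %in% network$molecules) {
    stop_lookup(sprintf("unknown molecule id '%s'", molecule_id))
  }
  d <- igraph::distances(network$graph, v = protein_id, to = molecule_id)[1, 1]
  if (is.infinite(d)) Inf else as.integer(d)
}

#' Generate nonbinding records by network distance
#'
#' Every protein-molecule pair whose shortest-path distance on the bipartite
#' interaction network is at least `threshold` hops becomes a candidate
#' negative; none of them duplicates a measured pair (distance >= 3 by
#' construction). Pairs in different components (infinite distance) are
#' excluded unless `include_disconnected = TRUE`: absence of network evidence
#' is not distance. With `max_per_protein` the candidates of each protein are
#' subsampled uniformly.
#'
#' @param network a `dti_network`
#' @param threshold minimum hop distance (default 7)
#' @param max_per_protein optional per-protein cap
#' @param seed integer seed for the subsampling
#' @param include_disconnected treat infinite distances as far (default FALSE)
#' @return interaction record tibble with label "nonbinding" and provenance
#'   "network_negative"
#' @export
sample_network_negatives <- function(network, threshold = 7L,
                                     max_per_protein = NULL, seed = 1L,
                                     include_disconnected = FALSE) {
  if (threshold < 1L) stop_validation("threshold must be >= 1")
  D <- igraph::distances(network$graph, v = network$proteins,
                         to = network$molecules)
  far <- D >= threshold
  if (!include_disconnected) far <- far & is.finite(D)
  out_p <- character(0)
  out_m <- character(0)
  withr::with_seed(seed, {
    for (pi in seq_along(network$proteins)) {
      mols <- network$molecules[far[pi, ]]
      if (!is.null(max_per_protein) && length(mols) > max_per_protein) {
        mols <- sort(mols)[sample.int(length(mols), max_per_protein)]
      }
      out_p <- c(out_p, rep(network$proteins[pi], length(mols)))
      out_m <- c(out_m, mols)
    }
  })
  interaction_records(out_p, out_m, rep("nonbinding", length(out_p)),
                      provenance = rep("network_negative", length(out_p)))
}

#' Cap for negative sampling that brings positive ratios to a target
#'
#' The stated purpose of the augmentation is to relieve annotation imbalance;
#' this helper computes, per protein, how many negatives bring its positive
#' ratio down to at most `target_ratio`.
#'
#' @param records measured interaction records
#' @param target_ratio desired maximum positive ratio (default 0.5)
#' @return named integer vector of needed negatives per protein
#' @export
negatives_needed <- function(records, target_ratio = 0.5) {
  pr <- positive_ratio(records)
  need <- ceiling(pr$n_binding / target_ratio) - pr$n
  setNames(pmax(0L, as.integer(need)), pr$protein_id)
}
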