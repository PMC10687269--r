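#' Greedy sequence clustering (cd-hit-style stand-in)
#'
#' Longest-first greedy clustering: each sequence joins the first existing
#' cluster whose representative has pairwise global-alignment identity at or
#' above the threshold, otherwise it founds a new cluster. Identity is the
#' number of matched positions of the global alignment divided by the longer
#' sequence length. Externally computed cluster maps can be passed straight
#' to [make_splits()] instead.
#'
#' @param sequences named character vector (protein id -> amino-acid sequence)
#' @param identity_threshold clustering threshold in (0, 1), default 0.4
#' @return named character vector protein id -> cluster id
#' @export
cluster_proteins <- function(sequences, identity_threshold = 0.4) {
  if (length(sequences) == 0L) stop_validation("sequences must be non-empty")
  if (any(!nzchar(sequences))) stop_validation("empty sequence")
  if (identity_threshold <= 0 || identity_threshold >= 1) {
    stop_validation("identity threshold must be in (0, 1)")
  }
  ord <- order(-nchar(sequences), names(sequences))
  ids <- names(sequences)[ord]
  seqs <- sequences[ord]
  blosum <- get_blosum62()
  reps <- character(0)
  assign <- character(length(ids))
  names(assign) <- ids
  for (i in seq_along(ids)) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      if (seq_identity(seqs[i], reps[ci], blosum) >= identity_threshold) {
        assign[ids[i]] <- paste0("C", ci)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, seqs[i])
      assign[ids[i]] <- paste0("C", length(reps))
    }
  }
  assign[names(sequences)]
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

seq_identity <- function(a, b, blosum = get_blosum62()) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = blosum,
    gapOpening = 10, gapExtension = 0.5
  )
  Biostrings::nmatch(al) / max(nchar(a), nchar(b))
}

# ---------------------------------------------------------------------------
# Bemis-Murcko scaffolds

# deterministic polynomial string hash (content-based, session-stable)
str_hash <- function(s) {
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 1e9
  formatC(h, width = 9, flag = "0")
}

# Weisfeiler-Lehman canonical key of a labelled graph
wl_graph_key <- function(labels, edge_i, edge_j, edge_labels, rounds = 3L) {
  n <- length(labels)
  if (n == 0L) return("")
  lab <- as.character(labels)
  for (r in seq_len(rounds)) {
    nbr <- vector("list", n)
    for (e in seq_along(edge_i)) {
      a <- edge_i[e]; b <- edge_j[e]
      nbr[[a]] <- c(nbr[[a]], paste0(edge_labels[e], ":", lab[b]))
      nbr[[b]] <- c(nbr[[b]], paste0(edge_labels[e], ":", lab[a]))
    }
    lab <- vapply(seq_len(n), function(v) {
      str_hash(paste0(lab[v], "|", paste(sort(nbr[[v]]), collapse = ",")))
    }, "")
  }
  str_hash(paste(sort(lab), collapse = "+"))
}

#' Bemis-Murcko scaffold key of a molecule
#'
#' Prunes terminal side-chain atoms until only ring systems and the linkers
#' between them remain, then emits a canonical graph-hash key of that
#' scaffold (atom label = element/aromaticity/ring flag, edge label = bond
#' type). Acyclic molecules map to the empty key `""`.
#'
#' @param smiles SMILES string (parse errors propagate), or a
#'   `molecule_graph`
#' @return character scaffold key
#' @export
scaffold_key <- function(smiles) {
  g <- if (inherits(smiles, "molecule_graph")) smiles else {
    build_molecule_graph(smiles, "scaffold_tmp")
  }
  n <- g$n_atoms
  if (n == 0L) return("")
  ei <- g$edges$i + 1L
  ej <- g$edges$j + 1L
  alive <- rep(TRUE, n)
  repeat {
    deg <- integer(n)
    keep <- alive[ei] & alive[ej]
    for (e in which(keep)) {
      deg[ei[e]] <- deg[ei[e]] + 1L
      deg[ej[e]] <- deg[ej[e]] + 1L
    }
    drop <- alive & deg <= 1L
    if (!any(drop)) break
    alive[drop] <- FALSE
  }
  if (!any(alive)) return("")
  idx <- which(alive)
  remap <- match(seq_len(n), idx)
  keep_e <- alive[ei] & alive[ej]
  labels <- paste(
    g$node_features[idx, "atomic_num"],
    g$node_features[idx, "aromatic"],
    g$node_features[idx, "in_ring"],
    sep = "."
  )
  wl_graph_key(labels, remap[ei[keep_e]], remap[ej[keep_e]],
               g$edges$bond_type[keep_e])
}

# ---------------------------------------------------------------------------
# Split construction

#' Build the train / transductive / semi-inductive / inductive partitions
#'
#' Scaffolds are split into train and test scaffold sets at
#' `train_scaffold_ratio` with zero overlap. Clusters containing any protein
#' with fewer than `min_molecules` associated molecules become test clusters,
#' the rest train clusters. The training set is 95% (by default) of the
#' train-cluster proteins crossed with train-scaffold molecules; the held-out
#' 5% of those proteins (still train scaffolds) form the transductive test
#' set; test-cluster proteins crossed with test-scaffold molecules form the
#' inductive test set; everything else is the semi-inductive test set
#' (optionally restricted to its strict definition: seen cluster, unseen
#' scaffold).
#'
#' @param records interaction record tibble
#' @param cluster_of named vector protein id -> cluster
#' @param scaffold_of named vector molecule id -> scaffold key
#' @param train_protein_ratio fraction of train-cluster proteins used for
#'   training
#' @param train_scaffold_ratio fraction of scaffolds assigned to training
#' @param min_molecules proteins below this interaction count drag their
#'   cluster into the test clusters
#' @param seed sampling seed
#' @param strict_semi_inductive drop test-cluster/train-scaffold records from
#'   the semi-inductive set instead of keeping the operational "rest" bucket
#' @return object of class `split_bundle`: tibbles `train`, `transductive`,
#'   `semi_inductive`, `inductive` plus the cluster/scaffold maps
#' @export
make_splits <- function(records, cluster_of, scaffold_of,
                        train_protein_ratio = 0.95,
                        train_scaffold_ratio = 0.95,
                        min_molecules = 20L, seed = 1L,
                        strict_semi_inductive = FALSE) {
  if (train_protein_ratio <= 0 || train_protein_ratio >= 1 ||
      train_scaffold_ratio <= 0 || train_scaffold_ratio >= 1) {
    stop_validation("ratios must lie strictly between 0 and 1")
  }
  if (!all(records$protein_id %in% names(cluster_of))) {
    stop_lookup("every record's protein needs a cluster")
  }
  if (!all(records$molecule_id %in% names(scaffold_of))) {
    stop_lookup("every record's molecule needs a scaffold")
  }
  records <- dplyr::arrange(records, .data$protein_id, .data$molecule_id)

  withr::with_seed(seed, {
    scaffolds <- sort(unique(scaffold_of[unique(records$molecule_id)]))
    n_train_scaf <- max(1L, min(length(scaffolds) - 1L,
                                round(train_scaffold_ratio * length(scaffolds))))
    train_scaffolds <- sort(sample(scaffolds, n_train_scaf))

    counts <- records |>
      dplyr::distinct(.data$protein_id, .data$molecule_id) |>
      dplyr::count(.data$protein_id)
    n_mols <- setNames(counts$n, counts$protein_id)
    prot_ids <- sort(unique(records$protein_id))
    small <- prot_ids[n_mols[prot_ids] < min_molecules]
    test_clusters <- sort(unique(cluster_of[small]))
    train_cluster_proteins <- prot_ids[!cluster_of[prot_ids] %in% test_clusters]

    # transductive proteins are sampled only from clusters that keep at least
    # one protein in training, so every transductive cluster stays "seen"
    n_trans <- length(train_cluster_proteins) -
      round(train_protein_ratio * length(train_cluster_proteins))
    cl_sizes <- table(cluster_of[train_cluster_proteins])
    pool <- train_cluster_proteins[
      cl_sizes[cluster_of[train_cluster_proteins]] >= 2L
    ]
    trans_proteins <- character(0)
    if (n_trans > 0L && length(pool) > 0L) {
      # at most one protein per multi-protein cluster leaves training
      pool_by_cl <- split(pool, cluster_of[pool])
      candidates <- sort(vapply(pool_by_cl, function(x) sample(x, 1L), ""))
      trans_proteins <- sort(sample(candidates,
                                    min(n_trans, length(candidates))))
    }
    train_proteins <- setdiff(train_cluster_proteins, trans_proteins)
  })

  mol_train <- scaffold_of[records$molecule_id] %in% train_scaffolds
  in_train_p <- records$protein_id %in% train_proteins
  in_trans_p <- records$protein_id %in% trans_proteins
  in_test_cl <- cluster_of[records$protein_id] %in% test_clusters

  idx_train <- in_train_p & mol_train
  idx_trans <- in_trans_p & mol_train
  idx_ind <- in_test_cl & !mol_train
  idx_semi <- !(idx_train | idx_trans | idx_ind)
  if (strict_semi_inductive) {
    idx_semi <- idx_semi & !in_test_cl & !mol_train
  }

  structure(
    list(
      train = records[idx_train, , drop = FALSE],
      transductive = records[idx_trans, , drop = FALSE],
      semi_inductive = records[idx_semi, , drop = FALSE],
      inductive = records[idx_ind, , drop = FALSE],
      cluster_of = cluster_of, scaffold_of = scaffold_of,
      train_scaffolds = train_scaffolds, test_clusters = test_clusters,
      train_proteins = sort(train_proteins),
      transductive_proteins = trans_proteins
    ),
    class = "split_bundle"
  )
}

#' @export
print.split_bundle <- function(x, ...) {
  cat(sprintf(
    paste0("<split_bundle: train %d | transductive %d | semi-inductive %d | ",
           "inductive %d records>\n"),
    nrow(x$train), nrow(x$transductive), nrow(x$semi_inductive),
    nrow(x$inductive)
  ))
  invisible(x)
}

#' Few-shot fine-tune/test sets
#'
#' For every protein of the combined semi-inductive and inductive sets with
#' at least `k_pos` binding and `k_neg` nonbinding records, samples exactly
#' k_pos + k_neg records into its fine-tuning set; the rest become its
#' few-shot test set. Proteins without enough of either class are excluded
#' from both.
#'
#' @param semi_inductive,inductive record tibbles (disjoint)
#' @param k_pos,k_neg per-class fine-tune sizes (default 5 + 5)
#' @param seed sampling seed
#' @return list with `finetune` and `test`, each a named list of record
#'   tibbles keyed by protein id
#' @export
make_fewshot <- function(semi_inductive, inductive, k_pos = 5L, k_neg = 5L,
                         seed = 1L) {
  combined <- dplyr::bind_rows(semi_inductive, inductive) |>
    dplyr::arrange(.data$protein_id, .data$molecule_id)
  finetune <- list()
  test <- list()
  withr::with_seed(seed, {
    for (pid in sort(unique(combined$protein_id))) {
      r <- combined[combined$protein_id == pid, , drop = FALSE]
      pos <- which(r$label == "binding")
      neg <- which(r$label == "nonbinding")
      if (length(pos) < k_pos || length(neg) < k_neg) next
      ft <- c(pos[sample.int(length(pos), k_pos)],
              neg[sample.int(length(neg), k_neg)])
      finetune[[pid]] <- r[ft, , drop = FALSE]
      test[[pid]] <- r[-ft, , drop = FALSE]
    }
  })
  list(finetune = finetune, test = test)
}
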