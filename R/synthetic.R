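#' Specification of a synthetic DTI benchmark
#'
#' The generator emulates the shapes of real inputs at desk scale: residue
#' chains with 3D coordinates and a sparse connected contact graph, per-
#' residue feature vectors with a planted pocket signature, molecule feature
#' graphs with a type signal, sequences drawn from mutated family consensi
#' (for clustering), scaffold labels from a finite pool (for scaffold
#' splitting), and binding labels from a pocket-molecule compatibility rule
#' with label noise: a molecule binds a protein iff its type matches the
#' protein's pocket type, flipped with probability `label_noise`.
#'
#' @param n_proteins,n_molecules benchmark sizes
#' @param residues_range range of chain lengths
#' @param embed_dim per-residue feature width
#' @param pocket_fraction fraction of residues forming the planted pocket
#' @param n_pocket_types number of pocket/molecule types
#' @param signature_magnitude L2 norm of the additive pocket signature
#' @param label_noise flip probability in [0, 0.5)
#' @param families number of sequence families (clusters)
#' @param mutation_rate per-position mutation rate within a family
#' @param mols_per_protein range of interaction counts per protein
#' @param n_scaffolds size of the scaffold label pool
#' @param feature_sd standard deviation of the background residue features
#' @param seed generator seed
#' @return list of class `synthetic_spec`
#' @export
synthetic_spec <- function(n_proteins = 64L, n_molecules = 400L,
                           residues_range = c(30L, 60L), embed_dim = 32L,
                           pocket_fraction = 0.15, n_pocket_types = 4L,
                           signature_magnitude = 1.0, label_noise = 0.05,
                           families = 16L, mutation_rate = 0.1,
                           mols_per_protein = c(12L, 70L),
                           n_scaffolds = 25L, feature_sd = 0.4, seed = 1L) {
  stopifnot(pocket_fraction > 0, pocket_fraction < 1,
            label_noise >= 0, label_noise < 0.5, n_pocket_types >= 1)
  structure(list(
    n_proteins = as.integer(n_proteins), n_molecules = as.integer(n_molecules),
    residues_range = as.integer(residues_range),
    embed_dim = as.integer(embed_dim), pocket_fraction = pocket_fraction,
    n_pocket_types = as.integer(n_pocket_types),
    signature_magnitude = signature_magnitude, label_noise = label_noise,
    families = as.integer(families), mutation_rate = mutation_rate,
    mols_per_protein = as.integer(mols_per_protein),
    n_scaffolds = as.integer(n_scaffolds), feature_sd = feature_sd,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# self-avoiding 3D random chain with 3.8 A steps and a 3.4 A excluded volume
random_chain <- function(n, step = 3.8, min_sep = 3.4, max_tries = 40L) {
  coords <- matrix(0, n, 3L)
  for (i in 2:n) {
    best <- NULL
    for (t in seq_len(max_tries)) {
      dir <- rnorm(3L)
      dir <- dir / sqrt(sum(dir^2))
      cand <- coords[i - 1L, ] + step * dir
      d2 <- rowSums(sweep(coords[seq_len(i - 2L), , drop = FALSE], 2L, cand)^2)
      if (i <= 2L || all(d2 >= min_sep^2)) {
        best <- cand
        break
      }
      best <- best %||% cand
    }
    coords[i, ] <- best
  }
  coords
}

# signature vectors shared across the benchmark: one unit vector per type
make_signatures <- function(spec) {
  sig <- matrix(rnorm(spec$n_pocket_types * spec$embed_dim),
                spec$n_pocket_types, spec$embed_dim)
  sig <- sig / sqrt(rowSums(sig^2)) * spec$signature_magnitude
  sig
}

#' Generate one synthetic protein with a planted pocket
#'
#' Draws a self-avoiding residue chain, marks the `ceil(pocket_fraction * n)`
#' residues nearest (in space) to a random seed residue as the pocket, adds
#' the pocket-type signature vector to their features, and emits a sequence
#' mutated from the consensus of the protein's family. Consumes the current
#' RNG stream.
#'
#' @param spec a [synthetic_spec()]
#' @param protein_id identifier
#' @param signatures type-signature matrix from the benchmark (rows = types)
#' @param family family index (determines the sequence consensus)
#' @param consensus family consensus sequence (character vector)
#' @param pocket_type planted pocket type (default: sampled)
#' @return list with `graph` (protein_graph), `pocket` (0-based indices),
#'   `pocket_type`, `sequence`, `family`
#' @export
make_protein <- function(spec, protein_id, signatures, family = 1L,
                         consensus = NULL,
                         pocket_type = sample.int(spec$n_pocket_types, 1L)) {
  n <- sample(seq(spec$residues_range[1], spec$residues_range[2]), 1L)
  coords <- random_chain(n)
  seed_res <- sample.int(n, 1L)
  k <- ceiling(spec$pocket_fraction * n)
  d2 <- rowSums(sweep(coords, 2L, coords[seed_res, ])^2)
  pocket <- sort(order(d2)[seq_len(k)])
  feats <- matrix(rnorm(n * spec$embed_dim, sd = spec$feature_sd),
                  n, spec$embed_dim)
  feats[pocket, ] <- feats[pocket, , drop = FALSE] +
    matrix(signatures[pocket_type, ], k, spec$embed_dim, byrow = TRUE)
  if (is.null(consensus)) {
    consensus <- sample(AA_ALPHABET, 100L, replace = TRUE)
  }
  seq_chars <- consensus[((seq_len(n) - 1L) %% length(consensus)) + 1L]
  mut <- runif(n) < spec$mutation_rate
  seq_chars[mut] <- sample(AA_ALPHABET, sum(mut), replace = TRUE)
  list(
    graph = build_protein_graph(coords, feats, protein_id),
    pocket = pocket - 1L,
    pocket_type = pocket_type,
    sequence = paste(seq_chars, collapse = ""),
    family = family
  )
}

#' Generate one synthetic molecule graph
#'
#' A random connected graph of 6-20 atoms whose categorical features follow
#' the OGB 9-tuple scheme; the molecule type is written into the atomic-number
#' feature of most atoms (the signal a learner must read), and a scaffold
#' label is drawn from a finite pool to exercise scaffold splitting. Consumes
#' the current RNG stream.
#'
#' @param spec a [synthetic_spec()]
#' @param molecule_id identifier
#' @param molecule_type type in 1..n_pocket_types (default: sampled uniformly)
#' @return list with `graph` (molecule_graph), `molecule_type`,
#'   `scaffold_label`
#' @export
make_molecule <- function(spec, molecule_id,
                          molecule_type = sample.int(spec$n_pocket_types, 1L)) {
  n <- sample(6:20, 1L)
  ei <- integer(0)
  ej <- integer(0)
  for (i in 2:n) {
    ei <- c(ei, sample.int(i - 1L, 1L))
    ej <- c(ej, i)
  }
  extra <- max(0L, round(n / 5))
  for (e in seq_len(extra)) {
    ab <- sort(sample.int(n, 2L))
    if (!any(ei == ab[1] & ej == ab[2])) {
      ei <- c(ei, ab[1])
      ej <- c(ej, ab[2])
    }
  }
  deg <- tabulate(c(ei, ej), n)
  vs <- feature_vocab_sizes()
  in_ring <- atoms_in_rings(n, data.frame(i = ei, j = ej))
  type_code <- 4L + molecule_type   # type written into the atomic-number slot
  atom_z <- ifelse(runif(n) < 0.85, type_code,
                   sample(c(5L, 6L, 7L, 8L, 14L, 15L), n, replace = TRUE))
  node_features <- cbind(
    atomic_num = encode_code(atom_z, vs$atom["atomic_num"]),
    chirality = 0L,
    formal_charge = encode_code(rep(5L, n), vs$atom["formal_charge"]),
    num_h = encode_code(sample(0:3, n, replace = TRUE), vs$atom["num_h"]),
    radical_e = 0L,
    hybridization = encode_code(sample(1:2, n, replace = TRUE),
                                vs$atom["hybridization"]),
    aromatic = sample(0:1, n, replace = TRUE),
    degree = encode_code(deg, vs$atom["degree"]),
    in_ring = as.integer(in_ring)
  )
  ne <- length(ei)
  edges <- tibble::tibble(
    i = ei - 1L, j = ej - 1L,
    bond_type = sample(0:3, ne, replace = TRUE),
    stereo = rep(0L, ne),
    conjugated = sample(0:1, ne, replace = TRUE)
  )
  list(
    graph = new_molecule_graph(molecule_id, NA_character_, node_features, edges),
    molecule_type = molecule_type,
    scaffold_label = paste0("SCAF", sample.int(spec$n_scaffolds, 1L))
  )
}

#' Generate a complete synthetic DTI benchmark
#'
#' Proteins with planted pockets, molecules with a type signal, and
#' interaction records labelled by the compatibility rule
#' `binding iff molecule_type == pocket_type`, flipped with probability
#' `label_noise`. All randomness comes from `spec$seed`.
#'
#' @param spec a [synthetic_spec()]
#' @return object of class `synthetic_benchmark`: named lists `proteins` and
#'   `molecules` (graphs), `records` (tibble), `truth` (list with pockets,
#'   pocket/molecule types, scaffold and family maps, signature matrix,
#'   sequences)
#' @export
make_benchmark <- function(spec) {
  withr::with_seed(spec$seed, {
    signatures <- make_signatures(spec)
    consensi <- lapply(seq_len(spec$families), function(f) {
      sample(AA_ALPHABET, 100L, replace = TRUE)
    })
    prot_ids <- sprintf("P%03d", seq_len(spec$n_proteins))
    fam <- rep(seq_len(spec$families), length.out = spec$n_proteins)
    proteins <- vector("list", spec$n_proteins)
    pockets <- vector("list", spec$n_proteins)
    pocket_type <- integer(spec$n_proteins)
    sequences <- character(spec$n_proteins)
    for (i in seq_len(spec$n_proteins)) {
      p <- make_protein(spec, prot_ids[i], signatures, family = fam[i],
                        consensus = consensi[[fam[i]]])
      proteins[[i]] <- p$graph
      pockets[[i]] <- p$pocket
      pocket_type[i] <- p$pocket_type
      sequences[i] <- p$sequence
    }
    names(proteins) <- prot_ids
    names(pockets) <- prot_ids

    mol_ids <- sprintf("M%04d", seq_len(spec$n_molecules))
    molecules <- vector("list", spec$n_molecules)
    molecule_type <- integer(spec$n_molecules)
    scaffold <- character(spec$n_molecules)
    for (i in seq_len(spec$n_molecules)) {
      m <- make_molecule(spec, mol_ids[i])
      molecules[[i]] <- m$graph
      molecule_type[i] <- m$molecule_type
      scaffold[i] <- m$scaffold_label
    }
    names(molecules) <- mol_ids

    rec_p <- character(0)
    rec_m <- character(0)
    for (i in seq_len(spec$n_proteins)) {
      nm <- sample(seq(spec$mols_per_protein[1], spec$mols_per_protein[2]), 1L)
      nm <- min(nm, spec$n_molecules)
      mols <- sort(sample(mol_ids, nm))
      rec_p <- c(rec_p, rep(prot_ids[i], nm))
      rec_m <- c(rec_m, mols)
    }
    match_lab <- pocket_type[match(rec_p, prot_ids)] ==
      molecule_type[match(rec_m, mol_ids)]
    flip <- runif(length(rec_p)) < spec$label_noise
    lab <- ifelse(xor(match_lab, flip), "binding", "nonbinding")
    records <- interaction_records(rec_p, rec_m, lab)
  })
  structure(
    list(
      spec = spec, proteins = proteins, molecules = molecules,
      records = records,
      truth = list(
        pockets = pockets,
        pocket_type = setNames(pocket_type, prot_ids),
        molecule_type = setNames(molecule_type, mol_ids),
        scaffold_of = setNames(scaffold, mol_ids),
        family_of = setNames(paste0("F", fam), prot_ids),
        sequences = setNames(sequences, prot_ids),
        signatures = signatures
      )
    ),
    class = "synthetic_benchmark"
  )
}

#' @export
print.synthetic_benchmark <- function(x, ...) {
  cat(sprintf(
    "<synthetic_benchmark: %d proteins, %d molecules, %d records (%.2f positive)>\n",
    length(x$proteins), length(x$molecules), nrow(x$records),
    mean(x$records$label == "binding")
  ))
  invisible(x)
}

#' Write the benchmark in the formats the real pipeline reads
#'
#' Coordinates as minimal PDB files (one CA atom per residue), per-protein
#' feature matrices as TSV, molecule graphs in the JSON graph-bundle
#' container, interactions as TSV, and ground truth (pockets, types,
#' scaffolds) as JSON. All synthetic, as the filenames say.
#'
#' @param bench a `synthetic_benchmark`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "structures"), showWarnings = FALSE)
  dir.create(file.path(dir, "features"), showWarnings = FALSE)
  for (pid in names(bench$proteins)) {
    g <- bench$proteins[[pid]]
    lines <- vapply(seq_len(g$n_residues), function(i) {
      sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
              i, i, g$coords[i, 1], g$coords[i, 2], g$coords[i, 3])
    }, "")
    writeLines(c(lines, "END"),
               file.path(dir, "structures", paste0("synthetic_", pid, ".pdb")))
    utils::write.table(
      g$node_features,
      file.path(dir, "features", paste0("synthetic_", pid, ".tsv")),
      sep = "\t", row.names = FALSE, col.names = FALSE
    )
  }
  write_graph_bundle(list(), bench$molecules,
                     file.path(dir, "synthetic_molecules.json"))
  utils::write.table(
    bench$records[, c("protein_id", "molecule_id", "label")],
    file.path(dir, "synthetic_interactions.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  jsonlite::write_json(
    list(
      pockets = bench$truth$pockets,
      pocket_type = as.list(bench$truth$pocket_type),
      molecule_type = as.list(bench$truth$molecule_type),
      scaffold_of = as.list(bench$truth$scaffold_of),
      family_of = as.list(bench$truth$family_of),
      sequences = as.list(bench$truth$sequences)
    ),
    file.path(dir, "synthetic_truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
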