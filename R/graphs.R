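#' Build a residue contact graph from 3D coordinates
#'
#' Residues are nodes; two residues are connected iff the Euclidean distance
#' between their representative points (conventionally the C-alpha atoms) is
#' strictly less than `cutoff` angstroms. Per-residue feature vectors (for
#' example rows of a protein language-model embedding matrix) ride along as
#' node features; they are consumed as a plain numeric matrix, never computed
#' here.
#'
#' @param coords n x 3 numeric matrix of residue coordinates in angstroms
#' @param node_features n x D numeric matrix of per-residue features
#' @param protein_id identifier string
#' @param cutoff contact distance threshold in angstroms (default 8)
#' @return an object of class `protein_graph` with fields `protein_id`,
#'   `n_residues`, `coords`, `node_features`, `adjacency` (symmetric 0/1
#'   matrix, zero diagonal), `edges` (tibble with `i`, `j`, `distance`,
#'   0-based, each undirected edge once)
#' @export
build_protein_graph <- function(coords, node_features, protein_id,
                                cutoff = 8.0) {
  coords <- as.matrix(coords)
  node_features <- as.matrix(node_features)
  if (ncol(coords) != 3L) stop_dimension("coords must have 3 columns")
  n <- nrow(coords)
  if (n < 2L) stop_validation("need at least 2 residues")
  if (nrow(node_features) != n) {
    stop_dimension(sprintf(
      "node_features has %d rows but coords has %d", nrow(node_features), n
    ))
  }
  check_finite_matrix(coords, "coords")
  d <- as.matrix(stats::dist(coords))
  adj <- (d < cutoff) * 1
  diag(adj) <- 0
  ut <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  edges <- tibble::tibble(
    i = unname(ut[, 1L]) - 1L, j = unname(ut[, 2L]) - 1L,
    distance = unname(d[ut])
  )
  structure(
    list(
      protein_id = as.character(protein_id), n_residues = n,
      coords = coords, node_features = node_features,
      adjacency = adj, edges = edges, cutoff = cutoff
    ),
    class = "protein_graph"
  )
}

#' @export
print.protein_graph <- function(x, ...) {
  cat(sprintf(
    "<protein_graph %s: %d residues, %d contact edges (< %g A), %d features>\n",
    x$protein_id, x$n_residues, nrow(x$edges), x$cutoff, ncol(x$node_features)
  ))
  invisible(x)
}

#' Read C-alpha coordinates from PDB-format text
#'
#' One coordinate row per residue in author order; for residues with
#' alternate locations the first altloc is kept.
#'
#' @param pdb_text character scalar holding PDB-format text
#' @param chain optional chain identifier; default all chains
#' @return list with `coords` (n x 3 matrix) and `residue_labels`
#'   (tibble: chain, resno, resname)
#' @export
read_structure <- function(pdb_text, chain = NULL) {
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(pdb_text, tf)
  pdb <- bio3d::read.pdb(tf, verbose = FALSE)
  at <- pdb$atom
  if (!is.null(chain)) {
    if (!chain %in% unique(at$chain)) {
      stop_lookup(sprintf("chain '%s' not present in structure", chain))
    }
    at <- at[at$chain == chain, , drop = FALSE]
  }
  ca <- at[at$elety == "CA" & at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (nrow(ca) == 0L) stop_validation("no C-alpha atoms in the selected chain")
  key <- paste(ca$chain, ca$resno, ca$insert %||% "", sep = "|")
  keep <- !duplicated(key)
  ca <- ca[keep, , drop = FALSE]
  list(
    coords = unname(as.matrix(ca[, c("x", "y", "z")])),
    residue_labels = tibble::tibble(
      chain = ca$chain, resno = ca$resno, resname = ca$resid
    )
  )
}

#' Map an index for truth pockets given residue labels
#'
#' Truth binding pockets are usually published as (chain, residue number)
#' lists; this turns them into 0-based node indices of the contact graph.
#'
#' @param residue_labels tibble from [read_structure()]
#' @param chain,resno vectors identifying the pocket residues
#' @return 0-based integer node indices
#' @export
residue_indices <- function(residue_labels, chain, resno) {
  key <- paste(residue_labels$chain, residue_labels$resno)
  want <- paste(chain, resno)
  idx <- match(want, key)
  if (anyNA(idx)) stop_lookup("some pocket residues not found in structure")
  idx - 1L
}

# ---------------------------------------------------------------------------
# Molecule graphs

parse_mol2 <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  a0 <- which(lines == "@<TRIPOS>ATOM")
  b0 <- which(lines == "@<TRIPOS>BOND")
  if (length(a0) == 0L) return(NULL)
  sect_lines <- function(start) {
    nxt <- which(startsWith(lines, "@<TRIPOS>") & seq_along(lines) > start)
    end <- if (length(nxt)) min(nxt) - 1L else length(lines)
    if (end < start + 1L) return(character(0))
    out <- lines[(start + 1L):end]
    out[nzchar(trimws(out))]
  }
  atom_lines <- sect_lines(a0)
  if (length(atom_lines) == 0L) return(NULL)
  af <- strsplit(trimws(atom_lines), "\\s+")
  atoms <- data.frame(
    element = vapply(af, function(x) sub("\\..*$", "", x[6]), ""),
    mol2_type = vapply(af, function(x) x[6], ""),
    stringsAsFactors = FALSE
  )
  bonds <- data.frame(i = integer(), j = integer(), type = character())
  if (length(b0)) {
    bl <- sect_lines(b0)
    if (length(bl)) {
      bf <- strsplit(trimws(bl), "\\s+")
      bonds <- data.frame(
        i = vapply(bf, function(x) as.integer(x[2]), 1L),
        j = vapply(bf, function(x) as.integer(x[3]), 1L),
        type = vapply(bf, function(x) x[4], ""),
        stringsAsFactors = FALSE
      )
    }
  }
  list(atoms = atoms, bonds = bonds)
}

parse_sdf_charges <- function(txt, n_atoms) {
  charges <- integer(n_atoms)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    k <- f[1]
    for (t in seq_len(k)) charges[f[2 * t]] <- f[2 * t + 1]
  }
  charges
}

#' Build a heavy-atom molecule graph from a SMILES string
#'
#' Atoms become nodes with the 9 categorical features of the OGB encoding and
#' bonds become undirected edges with 3 categorical features. Hydrogens are
#' implicit (heavy-atom graph). Parsing and aromaticity perception are done
#' by Open Babel; chirality, bond stereo and radical-electron counts are not
#' exposed by that toolkit and are emitted as "unspecified" codes.
#'
#' @param smiles SMILES string
#' @param molecule_id identifier string
#' @return an object of class `molecule_graph` with `node_features`
#'   (n x 9 integer matrix, 0-based codes), `edges` (tibble i, j 0-based plus
#'   `bond_type`, `stereo`, `conjugated`), `adjacency`
#' @export
build_molecule_graph <- function(smiles, molecule_id) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  inp <- paste0(smiles, "\t", molecule_id)
  mol2 <- suppressWarnings(suppressMessages(
    tryCatch(ChemmineOB::convertFormat("SMI", "MOL2", inp),
             error = function(e) "")
  ))
  parsed <- parse_mol2(mol2)
  if (is.null(parsed) || nrow(parsed$atoms) == 0L) {
    stop_parse(sprintf("unparsable SMILES: '%s'", smiles))
  }
  sdf <- suppressWarnings(suppressMessages(
    tryCatch(ChemmineOB::convertFormat("SMI", "SDF", inp),
             error = function(e) "")
  ))
  atoms <- parsed$atoms
  bonds <- parsed$bonds
  heavy <- atoms$element != "H"
  n_explicit_h <- integer(nrow(atoms))
  if (nrow(bonds)) {
    hi <- !heavy[bonds$i] & heavy[bonds$j]
    hj <- !heavy[bonds$j] & heavy[bonds$i]
    for (a in bonds$j[hi]) n_explicit_h[a] <- n_explicit_h[a] + 1L
    for (a in bonds$i[hj]) n_explicit_h[a] <- n_explicit_h[a] + 1L
  }
  idx_map <- cumsum(heavy)
  idx_map[!heavy] <- NA_integer_
  atoms <- atoms[heavy, , drop = FALSE]
  n <- nrow(atoms)
  charges_all <- parse_sdf_charges(sdf, length(heavy))
  charges <- charges_all[heavy]
  if (nrow(bonds)) {
    keep <- heavy[bonds$i] & heavy[bonds$j]
    bonds <- bonds[keep, , drop = FALSE]
    bonds$i <- idx_map[bonds$i]
    bonds$j <- idx_map[bonds$j]
  }
  degree <- integer(n)
  order_sum <- numeric(n)
  bond_order <- numeric(nrow(bonds))
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      bo <- switch(bonds$type[r], "1" = 1, "2" = 2, "3" = 3,
                   "ar" = 1.5, "am" = 1, 1)
      bond_order[r] <- bo
      degree[bonds$i[r]] <- degree[bonds$i[r]] + 1L
      degree[bonds$j[r]] <- degree[bonds$j[r]] + 1L
      order_sum[bonds$i[r]] <- order_sum[bonds$i[r]] + bo
      order_sum[bonds$j[r]] <- order_sum[bonds$j[r]] + bo
    }
  }
  aromatic_atom <- grepl("\\.ar$", atoms$mol2_type)
  if (nrow(bonds)) {
    ar_b <- bonds$type == "ar"
    aromatic_atom[bonds$i[ar_b]] <- TRUE
    aromatic_atom[bonds$j[ar_b]] <- TRUE
  }
  in_ring <- atoms_in_rings(n, bonds)
  z <- unname(ELEMENT_Z[atoms$element])
  z[is.na(z)] <- NA
  # implicit hydrogens by the standard-valence heuristic: effective valence
  # is shifted by the formal charge (N+ gains a slot, O- loses one)
  valence <- unname(STANDARD_VALENCE[atoms$element])
  num_h <- pmax(0, round(valence + charges - ceiling(order_sum)))
  num_h[is.na(num_h)] <- 0
  num_h <- num_h + n_explicit_h[heavy]
  vs <- feature_vocab_sizes()
  node_features <- cbind(
    atomic_num = encode_code(z - 1L, vs$atom["atomic_num"]),
    chirality = 0L,
    formal_charge = encode_code(charges + 5L, vs$atom["formal_charge"]),
    num_h = encode_code(num_h, vs$atom["num_h"]),
    radical_e = 0L,
    hybridization = encode_code(
      vapply(atoms$mol2_type, hybridization_code, 1L), vs$atom["hybridization"]
    ),
    aromatic = as.integer(aromatic_atom),
    degree = encode_code(degree, vs$atom["degree"]),
    in_ring = as.integer(in_ring)
  )
  rownames(node_features) <- NULL
  bond_type_code <- if (nrow(bonds)) {
    vapply(seq_len(nrow(bonds)), function(r) {
      switch(bonds$type[r], "1" = 0L, "2" = 1L, "3" = 2L, "ar" = 3L,
             "am" = 0L, misc_code(vs$bond["bond_type"]))
    }, 1L)
  } else integer(0)
  conjugated <- if (nrow(bonds)) {
    as.integer(bonds$type == "ar" |
      (aromatic_atom[bonds$i] & aromatic_atom[bonds$j]))
  } else integer(0)
  edges <- tibble::tibble(
    i = if (nrow(bonds)) bonds$i - 1L else integer(0),
    j = if (nrow(bonds)) bonds$j - 1L else integer(0),
    bond_type = bond_type_code,
    stereo = rep(0L, nrow(bonds)),
    conjugated = conjugated
  )
  new_molecule_graph(molecule_id, smiles, node_features, edges)
}

# atoms on any cycle: repeatedly strip degree-<=1 vertices; survivors with an
# edge are ring atoms
atoms_in_rings <- function(n, bonds) {
  if (n == 0L || nrow(bonds) == 0L) return(logical(n))
  alive <- rep(TRUE, n)
  ei <- bonds$i
  ej <- bonds$j
  repeat {
    deg <- integer(n)
    keep <- alive[ei] & alive[ej]
    for (r in which(keep)) {
      deg[ei[r]] <- deg[ei[r]] + 1L
      deg[ej[r]] <- deg[ej[r]] + 1L
    }
    drop <- alive & deg <= 1L
    if (!any(drop)) break
    alive[drop] <- FALSE
  }
  alive
}

new_molecule_graph <- function(molecule_id, smiles, node_features, edges) {
  n <- nrow(node_features)
  adj <- matrix(0, n, n)
  if (nrow(edges)) {
    ii <- edges$i + 1L
    jj <- edges$j + 1L
    adj[cbind(ii, jj)] <- 1
    adj[cbind(jj, ii)] <- 1
  }
  structure(
    list(
      molecule_id = as.character(molecule_id), smiles = smiles,
      n_atoms = n, node_features = node_features, edges = edges,
      adjacency = adj
    ),
    class = "molecule_graph"
  )
}

#' @export
print.molecule_graph <- function(x, ...) {
  cat(sprintf(
    "<molecule_graph %s: %d atoms, %d bonds>\n",
    x$molecule_id, x$n_atoms, nrow(x$edges)
  ))
  invisible(x)
}

#' Convert a binding affinity to a binary interaction label
#'
#' Affinities below 1000 nM are binding, above 1e6 nM nonbinding; the band in
#' between is excluded from the benchmark (neither rule fires).
#'
#' @param affinity_nM positive affinity value in nM
#' @param affinity_type one of Ki, Kd, IC50, EC50 (recorded, not used by the
#'   thresholds)
#' @param binding_max,nonbinding_min the two thresholds in nM
#' @return one of "binding", "nonbinding", "excluded"
#' @export
label_from_affinity <- function(affinity_nM,
                                affinity_type = c("Ki", "Kd", "IC50", "EC50"),
                                binding_max = 1000, nonbinding_min = 1e6) {
  if (!is.numeric(affinity_nM) || any(!is.finite(affinity_nM)) ||
      any(affinity_nM <= 0)) {
    stop_validation("affinity must be a positive finite value in nM")
  }
  out <- rep("excluded", length(affinity_nM))
  out[affinity_nM < binding_max] <- "binding"
  out[affinity_nM > nonbinding_min] <- "nonbinding"
  out
}
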