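# Categorical feature vocabularies for molecule graphs, following the Open
# Graph Benchmark encoding: each atom carries a 9-tuple of integer codes and
# each bond a 3-tuple. Codes are 0-based; the last code of every vocabulary
# is a reserved "misc" slot for categories outside the table.

#' Vocabulary sizes for the 9 atom features and 3 bond features
#'
#' Atom features (in order): atomic number, chirality, formal charge,
#' attached hydrogen count, radical electrons, hybridization, aromatic flag,
#' heavy-atom degree, in-ring flag. Bond features: bond type, bond stereo,
#' conjugated flag.
#'
#' @return named integer vectors in a list with elements `atom` and `bond`
#' @export
feature_vocab_sizes <- function() {
  list(
    atom = c(
      atomic_num = 120L, chirality = 5L, formal_charge = 12L, num_h = 10L,
      radical_e = 6L, hybridization = 6L, aromatic = 2L, degree = 12L,
      in_ring = 2L
    ),
    bond = c(bond_type = 5L, stereo = 7L, conjugated = 2L)
  )
}

misc_code <- function(size) size - 1L

# clamp a 0-based code into its vocabulary, sending unknowns to misc
encode_code <- function(value, size) {
  v <- as.integer(value)
  v[is.na(v) | v < 0L | v >= size - 1L] <- misc_code(size)
  v
}

# element symbol -> atomic number for common organic/biological elements
ELEMENT_Z <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12, Si = 14,
  P = 15, S = 16, Cl = 17, K = 19, Ca = 20, Mn = 25, Fe = 26, Co = 27,
  Ni = 28, Cu = 29, Zn = 30, Se = 34, Br = 35, I = 53
)

# hybridization codes: 0 = sp, 1 = sp2, 2 = sp3, 3 = sp3d, 4 = sp3d2, 5 = misc
hybridization_code <- function(mol2_type) {
  suffix <- sub("^[A-Za-z]+\\.?", "", mol2_type)
  switch(suffix,
    "1" = 0L, "2" = 1L, "ar" = 1L, "3" = 2L,
    "am" = 1L, "co2" = 1L, "pl3" = 1L, "O2" = 1L,
    5L
  )
}

# standard valences used for the implicit-hydrogen heuristic
STANDARD_VALENCE <- c(
  C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1, I = 1, B = 3,
  Si = 4, Se = 2
)
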