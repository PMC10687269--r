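test_that("contact edges follow the strict 8 A rule", {
  coords <- rbind(c(0, 0, 0), c(5, 0, 0))
  g <- build_protein_graph(coords, matrix(0, 2, 4), "p")
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$distance, 5)

  coords <- rbind(c(0, 0, 0), c(7, 0, 0), c(14, 0, 0))
  g <- build_protein_graph(coords, matrix(0, 3, 4), "p")
  expect_equal(nrow(g$edges), 2L)
  expect_setequal(paste(g$edges$i, g$edges$j), c("0 1", "1 2"))

  # boundary: exactly 8 A is NOT an edge
  coords <- rbind(c(0, 0, 0), c(8, 0, 0))
  g <- build_protein_graph(coords, matrix(0, 2, 4), "p")
  expect_equal(nrow(g$edges), 0L)
})

test_that("contact graph matches the O(n^2) brute-force oracle", {
  for (seed in 1:5) {
    n <- c(30L, 80L, 120L, 200L, 50L)[seed]
    coords <- withr::with_seed(seed, matrix(rnorm(n * 3, sd = 8), n, 3))
    g <- build_protein_graph(coords, matrix(0, n, 2), "p")
    oe <- oracle_contact_edges(coords)
    if (is.null(oe)) {
      expect_equal(nrow(g$edges), 0L)
    } else {
      expect_equal(nrow(g$edges), nrow(oe))
      got <- g$edges[order(g$edges$i, g$edges$j), ]
      oe <- oe[order(oe[, 1], oe[, 2]), , drop = FALSE]
      expect_equal(got$i, oe[, 1])
      expect_equal(got$j, oe[, 2])
      expect_equal(got$distance, oe[, 3], tolerance = 1e-12)
    }
    # adjacency invariants
    expect_true(all(diag(g$adjacency) == 0))
    expect_identical(g$adjacency, t(g$adjacency))
  }
})

test_that("edge set is invariant to rigid-body transforms", {
  n <- 40L
  coords <- withr::with_seed(11, matrix(rnorm(n * 3, sd = 6), n, 3))
  g1 <- build_protein_graph(coords, matrix(0, n, 2), "p")
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0),
             c(0, 0, 1))
  coords2 <- coords %*% R + matrix(c(10, -3, 5), n, 3, byrow = TRUE)
  g2 <- build_protein_graph(coords2, matrix(0, n, 2), "p")
  expect_equal(g1$edges$i, g2$edges$i)
  expect_equal(g1$edges$j, g2$edges$j)
  expect_equal(g1$edges$distance, g2$edges$distance, tolerance = 1e-9)
})

test_that("protein graph validates inputs", {
  expect_error(build_protein_graph(matrix(0, 3, 3), matrix(0, 2, 4), "p"),
               class = "metabind_dimension_error")
  bad <- matrix(c(0, 0, 0, NA, 1, 1), 2, 3, byrow = TRUE)
  expect_error(build_protein_graph(bad, matrix(0, 2, 4), "p"),
               class = "metabind_validation_error")
})

make_pdb <- function(rows) {
  paste(c(vapply(seq_len(nrow(rows)), function(i) {
    sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, rows$elety[i], rows$resname[i], rows$chain[i], rows$resno[i],
            rows$x[i], rows$y[i], rows$z[i])
  }, ""), "END"), collapse = "\n")
}

test_that("read_structure extracts one CA per residue in author order", {
  rows <- data.frame(
    elety = c("N", "CA", "C", "CA"), resname = c("ALA", "ALA", "ALA", "GLY"),
    chain = "A", resno = c(1, 1, 1, 2),
    x = c(0, 1, 2, 5), y = 0, z = 0
  )
  st <- read_structure(make_pdb(rows))
  expect_equal(nrow(st$coords), 2L)
  expect_equal(st$coords[, 1], c(1, 5))
  expect_equal(st$residue_labels$resname, c("ALA", "GLY"))
})

test_that("read_structure filters chains and handles altlocs", {
  rows <- data.frame(
    elety = "CA", resname = "ALA",
    chain = c("A", "A", "B"), resno = c(1, 2, 1),
    x = c(0, 4, 9), y = 0, z = 0
  )
  st <- read_structure(make_pdb(rows), chain = "A")
  expect_equal(nrow(st$coords), 2L)
  expect_true(all(st$residue_labels$chain == "A"))
  expect_error(read_structure(make_pdb(rows), chain = "Z"),
               class = "metabind_lookup_error")

  # altloc duplicates: one row per (chain, resseq), first kept
  pdb_alt <- paste(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.50  0.00           C",
    "ATOM      2  CA BALA A   1       0.500   0.000   0.000  0.50  0.00           C",
    "ATOM      3  CA  GLY A   2       4.000   0.000   0.000  1.00  0.00           C",
    "END", sep = "\n")
  st <- read_structure(pdb_alt)
  expect_equal(nrow(st$coords), 2L)
  expect_equal(st$coords[1, 1], 0)
})

test_that("molecule graphs follow the OGB-style encoding", {
  m <- build_molecule_graph("C", "methane")
  expect_equal(m$n_atoms, 1L)
  expect_equal(nrow(m$edges), 0L)
  expect_equal(m$node_features[1, "atomic_num"], c(atomic_num = 5L)) # Z=6, 0-based

  e <- build_molecule_graph("CC", "ethane")
  expect_equal(e$n_atoms, 2L)
  expect_equal(nrow(e$edges), 1L)
  expect_equal(e$edges$bond_type, 0L)        # single
  expect_equal(e$edges$conjugated, 0L)
  expect_equal(unname(e$node_features[, "num_h"]), c(3L, 3L))

  b <- build_molecule_graph("c1ccccc1", "benzene")
  expect_equal(b$n_atoms, 6L)
  expect_equal(nrow(b$edges), 6L)
  expect_true(all(b$node_features[, "aromatic"] == 1L))
  expect_true(all(b$node_features[, "in_ring"] == 1L))
  expect_true(all(b$edges$bond_type == 3L))  # aromatic
  expect_identical(b$adjacency, t(b$adjacency))
  expect_true(all(b$node_features[, "degree"] == 2L))
})

test_that("unparsable SMILES raise a parse error naming the string", {
  expect_error(build_molecule_graph("C1CC(", "bad"),
               regexp = "C1CC\\(", class = "metabind_parse_error")
})

test_that("affinity labels partition (0, Inf) into three monotone bands", {
  expect_equal(label_from_affinity(500), "binding")
  expect_equal(label_from_affinity(2e6), "nonbinding")
  expect_equal(label_from_affinity(5e4), "excluded")
  expect_error(label_from_affinity(-1), class = "metabind_validation_error")

  # monotonicity: increasing affinity never moves toward "binding"
  rank_of <- c(binding = 1, excluded = 2, nonbinding = 3)
  x <- sort(10^runif(200, -2, 8))
  r <- rank_of[label_from_affinity(x)]
  expect_true(all(diff(r) >= 0))
  # boundary values fall in the excluded band (strict inequalities)
  expect_equal(label_from_affinity(1000), "excluded")
  expect_equal(label_from_affinity(1e6), "excluded")
})

test_that("graph bundles round-trip through JSON", {
  fx <- tiny_part(n_mols = 2L)
  tf <- withr::local_tempfile(fileext = ".json")
  write_graph_bundle(list(fx$protein$graph), fx$molecules, tf)
  rb <- read_graph_bundle(tf)
  expect_equal(rb$proteins[[1]]$adjacency, fx$protein$graph$adjacency)
  expect_equal(rb$proteins[[1]]$node_features, fx$protein$graph$node_features)
  expect_equal(rb$molecules[[2]]$node_features, fx$molecules[[2]]$node_features)
  expect_equal(rb$molecules[[2]]$edges$bond_type, fx$molecules[[2]]$edges$bond_type)
})
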