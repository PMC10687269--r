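# Shared fixtures and independent oracles used across the test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_base_config <- function(...) {
  base_config(
    protein_widths = c(8L, 6L, 5L), molecule_embed_dim = 6L,
    molecule_widths = c(6L, 5L), assign_hidden = 4L,
    critic_hidden = c(6L, 4L), classifier_hidden = c(6L, 4L),
    mi_inner_steps = 0L, ...
  )
}

tiny_spec <- function(...) {
  synthetic_spec(embed_dim = 8L, residues_range = c(10L, 14L), ...)
}

# a small prepared task part with labels, under a fixed seed
tiny_part <- function(cfg = tiny_base_config(), n_mols = 3L, seed = 7L) {
  sp <- tiny_spec()
  withr::with_seed(seed, {
    sig <- metabind:::make_signatures(sp)
    pr <- make_protein(sp, "P1", sig)
    mols <- lapply(seq_len(n_mols), function(i) {
      make_molecule(sp, paste0("M", i))$graph
    })
    labels <- rep_len(c(1, 0), n_mols)
  })
  list(part = metabind:::prepare_part(pr$graph, mols, labels, cfg),
       protein = pr, molecules = mols)
}

# O(n^2) brute-force contact-edge oracle
oracle_contact_edges <- function(coords, cutoff = 8) {
  n <- nrow(coords)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (d < cutoff) out <- rbind(out, c(i - 1, j - 1, d))
    }
  }
  out
}

# hand-rolled breadth-first search on a bipartite edge list
oracle_bfs_distance <- function(edges, from, to) {
  nodes <- unique(c(edges$protein_id, edges$molecule_id, from, to))
  adj <- lapply(setNames(vector("list", length(nodes)), nodes), function(x) character(0))
  for (r in seq_len(nrow(edges))) {
    p <- edges$protein_id[r]
    m <- edges$molecule_id[r]
    adj[[p]] <- c(adj[[p]], m)
    adj[[m]] <- c(adj[[m]], p)
  }
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  dist[from] <- 0
  queue <- from
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist[to]
}

# pairwise-identity + connected-components clustering oracle
oracle_cluster_components <- function(sequences, threshold) {
  n <- length(sequences)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        id <- metabind:::seq_identity(sequences[i], sequences[j])
        adj[i, j] <- adj[j, i] <- id >= threshold
      }
    }
  }
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      stack <- i
      while (length(stack)) {
        v <- stack[1]
        stack <- stack[-1]
        if (comp[v] == 0L) {
          comp[v] <- cur
          stack <- c(stack, which(adj[v, ] & comp == 0L))
        }
      }
    }
  }
  comp
}

# random bipartite interaction records
random_records <- function(n_prot, n_mol, n_edges, seed) {
  withr::with_seed(seed, {
    p <- sprintf("P%02d", sample.int(n_prot, n_edges, replace = TRUE))
    m <- sprintf("M%02d", sample.int(n_mol, n_edges, replace = TRUE))
  })
  lab <- rep_len(c("binding", "nonbinding"), n_edges)
  unique(interaction_records(p, m, lab))
}

expect_row_stochastic <- function(Z, tol = 1e-6) {
  expect_true(all(Z >= 0 & Z <= 1))
  expect_true(max(abs(rowSums(Z) - 1)) < tol)
}

# finite-difference gradient of a scalar function of a flat vector
fd_grad <- function(f, v, idx = seq_along(v), eps = 1e-5) {
  vapply(idx, function(i) {
    vp <- v; vm <- v
    vp[i] <- vp[i] + eps
    vm[i] <- vm[i] - eps
    (f(vp) - f(vm)) / (2 * eps)
  }, 0)
}
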