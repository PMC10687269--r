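test_that("gcn_layer matches the dense normalized-propagation oracle", {
  # single node, identity weights: output equals the (nonnegative) input
  x <- matrix(c(0.3, 0.8), 1)
  out <- gcn_layer(x, matrix(0, 1, 1), diag(2), c(0, 0))
  expect_equal(out, x)

  # a large negative bias floors everything at zero
  out <- gcn_layer(x, matrix(0, 1, 1), diag(2), c(-100, -100))
  expect_true(all(out == 0))

  for (seed in 1:20) {
    withr::with_seed(seed, {
      n <- 6L
      A <- matrix(rbinom(n * n, 1, 0.4), n, n)
      A <- 1 * ((A + t(A)) > 0)
      diag(A) <- 0
      X <- matrix(rnorm(n * 3), n, 3)
      W <- matrix(rnorm(3 * 4), 3, 4)
      b <- rnorm(4)
    })
    # explicit D^{-1/2}(A+I)D^{-1/2} computation
    Ai <- A + diag(n)
    Dm <- diag(1 / sqrt(rowSums(Ai)))
    oracle <- pmax(Dm %*% Ai %*% Dm %*% X %*% W +
                     matrix(b, n, 4, byrow = TRUE), 0)
    expect_equal(gcn_layer(X, A, W, b), oracle, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  expect_error(gcn_layer(matrix(0, 2, 3), matrix(0, 2, 2), diag(4), numeric(4)),
               class = "metabind_dimension_error")
})

test_that("encoders are permutation equivariant/invariant and match unrolls", {
  cfg <- tiny_base_config()
  params <- withr::with_seed(1, init_base_params(cfg))
  fx <- tiny_part(cfg)
  pg <- fx$protein$graph
  H <- encode_protein(pg, params$theta_P, cfg)
  expect_equal(dim(H), c(pg$n_residues, 5L))

  # hand-unrolled two-layer oracle
  Ahat <- normalize_adjacency(pg$adjacency)
  H1 <- pmax(Ahat %*% pg$node_features %*% params$theta_P[[1]]$W +
               matrix(params$theta_P[[1]]$b, pg$n_residues, 6, byrow = TRUE), 0)
  H2 <- pmax(Ahat %*% H1 %*% params$theta_P[[2]]$W +
               matrix(params$theta_P[[2]]$b, pg$n_residues, 5, byrow = TRUE), 0)
  expect_equal(H, H2, tolerance = 1e-6)

  # zero weights give zero embeddings
  zeroed <- par_map(params$theta_P, function(x) x * 0)
  expect_true(all(encode_protein(pg, zeroed, cfg) == 0))

  # permuting residues permutes rows; pooled molecule embedding is invariant
  perm <- withr::with_seed(3, sample(pg$n_residues))
  pg2 <- build_protein_graph(pg$coords[perm, ], pg$node_features[perm, ], "p")
  expect_equal(encode_protein(pg2, params$theta_P, cfg), H[perm, ],
               tolerance = 1e-9, ignore_attr = TRUE)

  mg <- fx$molecules[[1]]
  em <- encode_molecule(mg, params$theta_M, cfg)
  expect_length(em$embedding, 5L)
  aperm_idx <- withr::with_seed(4, sample(mg$n_atoms))
  mg2 <- metabind:::new_molecule_graph(
    "m2", NA, mg$node_features[aperm_idx, , drop = FALSE],
    tibble::tibble(
      i = match(mg$edges$i + 1L, aperm_idx) - 1L,
      j = match(mg$edges$j + 1L, aperm_idx) - 1L,
      bond_type = mg$edges$bond_type, stereo = mg$edges$stereo,
      conjugated = mg$edges$conjugated
    )
  )
  em2 <- encode_molecule(mg2, params$theta_M, cfg)
  expect_equal(em2$embedding, em$embedding, tolerance = 1e-9)
})

test_that("sib_assign produces saturating row-stochastic assignments", {
  # zero weights -> equal logits -> every row (0.5, 0.5)
  phi1 <- lapply(metabind:::mlp_init(c(6L, 4L, 2L)), function(l) {
    list(W = l$W * 0, b = l$b * 0)
  })
  Z <- sib_assign(matrix(rnorm(12), 4, 3), rnorm(3), phi1)
  expect_equal(Z, matrix(0.5, 4, 2), ignore_attr = TRUE)

  # saturated logits via the bias of a weight-free net
  phi1[[2]]$b <- c(10, -10)
  Z <- sib_assign(matrix(rnorm(12), 4, 3), rnorm(3), phi1)
  expect_true(all(abs(Z[, 1] - 1) < 1e-4))

  # normalization sweep under random parameters
  withr::with_seed(8, {
    phi1 <- metabind:::mlp_init(c(6L, 5L, 2L))
    Z <- sib_assign(matrix(rnorm(1000 * 3), 1000, 3),
                    rnorm(3), phi1)
  })
  expect_row_stochastic(Z)
})

test_that("subgraph_embedding is row 0 of Z^T H", {
  withr::with_seed(2, {
    H <- matrix(rnorm(8 * 4), 8, 4)
    u <- runif(8)
  })
  # hard indicator selects the set sum
  Zh <- cbind(rep(c(1, 0), 4), rep(c(0, 1), 4))
  expect_equal(subgraph_embedding(Zh, H), colSums(H[c(1, 3, 5, 7), ]))
  # uniform Z halves the column sums
  Zu <- matrix(0.5, 8, 2)
  expect_equal(subgraph_embedding(Zu, H), colSums(H) / 2)
  # random Z equals the dense product oracle
  Zr <- cbind(u, 1 - u)
  expect_equal(subgraph_embedding(Zr, H), drop((t(Zr) %*% H)[1, ]),
               tolerance = 1e-12)
  expect_error(subgraph_embedding(Zr[1:3, ], H),
               class = "metabind_dimension_error")
})

test_that("connectivity loss has its closed-form values and matrix oracle", {
  # two disconnected triangles, component-indicator Z -> 0
  A <- matrix(0, 6, 6)
  tri <- rbind(c(1, 2), c(2, 3), c(1, 3))
  for (r in seq_len(3)) {
    A[tri[r, 1], tri[r, 2]] <- A[tri[r, 2], tri[r, 1]] <- 1
    A[tri[r, 1] + 3, tri[r, 2] + 3] <- A[tri[r, 2] + 3, tri[r, 1] + 3] <- 1
  }
  Z <- rbind(matrix(rep(c(1, 0), 3), 3, 2, byrow = TRUE),
             matrix(rep(c(0, 1), 3), 3, 2, byrow = TRUE))
  expect_lt(connectivity_loss(Z, A), 1e-9)

  # uniform Z on any graph with edges -> 0.25
  withr::with_seed(5, {
    B <- matrix(rbinom(64, 1, 0.3), 8, 8)
  })
  B <- 1 * ((B + t(B)) > 0)
  diag(B) <- 0
  if (sum(B) == 0) B[1, 2] <- B[2, 1] <- 1
  expect_equal(connectivity_loss(matrix(0.5, 8, 2), B), 0.25, tolerance = 1e-12)

  # random Z: step-by-step matrix oracle
  for (seed in 1:20) {
    withr::with_seed(seed, {
      u <- runif(8)
      A8 <- matrix(rbinom(64, 1, 0.4), 8, 8)
    })
    A8 <- 1 * ((A8 + t(A8)) > 0)
    diag(A8) <- 0
    Zr <- cbind(u, 1 - u)
    S <- t(Zr) %*% A8 %*% Zr
    p <- diag(S / (rowSums(S) + 1e-12))
    expect_equal(connectivity_loss(Zr, A8), mean((p - 1)^2), tolerance = 1e-12)
  }
})

test_that("connectivity gradient descent hardens a two-component assignment", {
  # two 4-cliques joined by nothing: gradient flow on L_conn alone should
  # push a near-uniform Z toward hard component assignments
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 1
  A[5:8, 5:8] <- 1
  diag(A) <- 0
  withr::with_seed(10, {
    Z <- matrix(0.5, 8, 2) + matrix(rnorm(16, sd = 0.02), 8, 2)
  })
  Z <- Z / rowSums(Z)
  hardness <- function(Z) mean(pmax(Z[, 1], Z[, 2]))
  h0 <- hardness(Z)
  hs <- numeric(200)
  for (it in 1:200) {
    g <- metabind:::conn_loss_grad(Z, A)
    # project the gradient step back onto row-stochastic matrices
    Z <- Z - 0.5 * g$dZ
    Z <- pmin(pmax(Z, 1e-6), 1)
    Z <- Z / rowSums(Z)
    hs[it] <- hardness(Z)
  }
  expect_gt(hs[200], h0)
  expect_gt(hs[200], 0.95)
  # trend is monotone up to the wiggle introduced by the projection step
  expect_true(all(cummax(hs) - hs < 0.02))
})

test_that("the DV proxy has its closed forms", {
  d <- 3L
  # constant critic: zero weights, bias c in the last layer
  for (N in 2:10) {
    phi2 <- lapply(metabind:::mlp_init(c(2 * d, 4L, 1L)), function(l) {
      list(W = l$W * 0, b = l$b * 0)
    })
    phi2[[2]]$b <- 1.7
    W <- matrix(rnorm(N * d), N, d)
    S <- matrix(rnorm(N * d), N, d)
    expect_equal(mi_proxy_loss(W, S, phi2), -log(N - 1), tolerance = 1e-9)
  }

  # N = 2 hand formula with an arbitrary critic
  phi2 <- withr::with_seed(3, metabind:::mlp_init(c(2 * d, 4L, 1L)))
  W <- withr::with_seed(4, matrix(rnorm(2 * d), 2, d))
  S <- withr::with_seed(5, matrix(rnorm(2 * d), 2, d))
  critic <- function(g, s) drop(metabind:::mlp_forward(matrix(c(g, s), 1), phi2)$out)
  a11 <- critic(W[1, ], S[1, ])
  a22 <- critic(W[2, ], S[2, ])
  a12 <- critic(W[1, ], S[2, ])
  a21 <- critic(W[2, ], S[1, ])
  expect_equal(mi_proxy_loss(W, S, phi2),
               (a11 + a22) / 2 - log((exp(a12) + exp(a21)) / 2),
               tolerance = 1e-9)

  # joint permutation invariance
  N <- 5L
  W <- withr::with_seed(6, matrix(rnorm(N * d), N, d))
  S <- withr::with_seed(7, matrix(rnorm(N * d), N, d))
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(mi_proxy_loss(W, S, phi2),
               mi_proxy_loss(W[perm, ], S[perm, ], phi2), tolerance = 1e-12)

  expect_error(mi_proxy_loss(W[1, , drop = FALSE], S[1, , drop = FALSE], phi2),
               class = "metabind_validation_error")
})

test_that("critic ascent increases the DV bound, separating dependent pairs", {
  d <- 4L
  N <- 12L
  wins <- 0L
  for (seed in 1:20) {
    withr::with_seed(seed, {
      W <- matrix(rnorm(N * d), N, d)
      S_dep <- W + matrix(rnorm(N * d, sd = 0.1), N, d)
      S_shuf <- S_dep[sample(N), ]
      phi2a <- metabind:::mlp_init(c(2 * d, 8L, 1L))
      phi2b <- phi2a
    })
    phi2a <- mi_critic_ascent(W, S_dep, phi2a, steps = 60L, lr = 0.05)
    phi2b <- mi_critic_ascent(W, S_shuf, phi2b, steps = 60L, lr = 0.05)
    dep <- mi_proxy_loss(W, S_dep, phi2a)
    shuf <- mi_proxy_loss(W, S_shuf, phi2b)
    wins <- wins + (dep > shuf)
  }
  # sign test at alpha = 0.05: dependent pairing wins significantly often
  expect_lt(binom.test(wins, 20L, 0.5, alternative = "greater")$p.value, 0.05)
})

test_that("classification and BCE have their textbook values", {
  expect_equal(bce_loss(1, 0.5), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(1, 0.9), -log(0.9), tolerance = 1e-12)
  expect_lt(bce_loss(0, 1e-9), 1e-6)   # clamp keeps the limit finite
  expect_true(is.finite(bce_loss(1, 0)))

  cfg <- tiny_base_config()
  params <- withr::with_seed(1, init_base_params(cfg))
  p <- classify(rnorm(5), rnorm(5), params$theta_cls)
  expect_true(p > 0 && p < 1)
  expect_error(classify(rnorm(2), rnorm(2), params$theta_cls),
               class = "metabind_dimension_error")
})

test_that("base_forward degenerates to pure BCE with both weights at zero", {
  cfg <- tiny_base_config(lambda1 = 0, lambda2 = 0)
  params <- withr::with_seed(1, init_base_params(cfg))
  fx <- tiny_part(cfg)
  out <- base_forward(fx$protein$graph, fx$molecules[[1]], params, cfg,
                      label = 1, mi_batch = fx$molecules[-1])
  expect_equal(out$loss, bce_loss(1, out$yhat), tolerance = 1e-12)
  expect_row_stochastic(out$Z)
})

test_that("base_forward assembles the three-term loss (critic frozen)", {
  cfg <- tiny_base_config()  # mi_inner_steps = 0
  params <- withr::with_seed(1, init_base_params(cfg))
  fx <- tiny_part(cfg, n_mols = 3L)
  out <- base_forward(fx$protein$graph, fx$molecules[[1]], params, cfg,
                      label = 1, mi_batch = fx$molecules[-1])

  # component-wise oracle
  H <- encode_protein(fx$protein$graph, params$theta_P, cfg)
  gm <- lapply(fx$molecules, function(m) encode_molecule(m, params$theta_M, cfg)$embedding)
  Z1 <- sib_assign(H, gm[[1]], params$phi1)
  s <- lapply(seq_len(3), function(j) {
    subgraph_embedding(sib_assign(H, gm[[j]], params$phi1), H)
  })
  yhat <- classify(gm[[1]], s[[1]], params$theta_cls)
  gw <- colMeans(H)
  lmi <- mi_proxy_loss(rbind(gw, gw, gw), do.call(rbind, s), params$phi2)
  expected <- bce_loss(1, yhat) + cfg$lambda1 * connectivity_loss(Z1, fx$protein$graph$adjacency) +
    cfg$lambda2 * lmi
  expect_equal(out$yhat, yhat, tolerance = 1e-9)
  expect_equal(out$loss, expected, tolerance = 1e-9)
})

test_that("random-Z ablation draws seeded row-stochastic Z with no phi1 gradient", {
  cfg <- tiny_base_config(sib = "random")
  params <- withr::with_seed(1, init_base_params(cfg))
  fx <- tiny_part(cfg)
  r1 <- withr::with_seed(5, metabind:::task_loss_grad(params, fx$part, cfg))
  r2 <- withr::with_seed(5, metabind:::task_loss_grad(params, fx$part, cfg))
  expect_identical(r1$aux$Z, r2$aux$Z)
  expect_row_stochastic(r1$aux$Z[[1]])
  expect_equal(metabind:::par_norm(r1$grads$phi1), 0)
  # but the classifier still receives gradients
  expect_gt(metabind:::par_norm(r1$grads$theta_cls), 0)
})

test_that("analytic task gradients match central finite differences", {
  for (mode in c("sib", "off")) {
    cfg <- tiny_base_config(sib = mode)
    params <- withr::with_seed(1, init_base_params(cfg))
    fx <- tiny_part(cfg, n_mols = 3L)
    r <- metabind:::task_loss_grad(params, fx$part, cfg)
    tmpl <- params[c("theta_P", "theta_M", "phi1", "theta_cls")]
    v0 <- metabind:::par_flatten(tmpl)
    ga <- metabind:::par_flatten(r$grads)
    f <- function(v) {
      p2 <- params
      p2[names(tmpl)] <- metabind:::par_unflatten(tmpl, v)
      metabind:::task_loss_grad(p2, fx$part, cfg, want_grad = FALSE)$loss
    }
    idx <- withr::with_seed(2, sample(length(v0), 50))
    expect_lt(max(abs(fd_grad(f, v0, idx) - ga[idx])), 1e-6)
  }
})

test_that("whole pipeline is invariant to residue relabeling", {
  cfg <- tiny_base_config()
  params <- withr::with_seed(1, init_base_params(cfg))
  fx <- tiny_part(cfg)
  pg <- fx$protein$graph
  out1 <- base_forward(pg, fx$molecules[[1]], params, cfg)
  perm <- withr::with_seed(6, sample(pg$n_residues))
  pg2 <- build_protein_graph(pg$coords[perm, ], pg$node_features[perm, ], "p")
  out2 <- base_forward(pg2, fx$molecules[[1]], params, cfg)
  expect_equal(out2$yhat, out1$yhat, tolerance = 1e-6)
  expect_equal(out2$Z, out1$Z[perm, ], tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("checkpoints round-trip exactly", {
  cfg <- tiny_base_config()
  meta <- meta_config(inner_steps = 2L, attention_dim = 4L)
  params <- withr::with_seed(1, init_meta_params(cfg, meta))
  model <- structure(list(params = params,
                          config = list(base = cfg, meta = meta)),
                     class = "metabind_model")
  tf <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(model, tf)
  back <- load_checkpoint(tf)
  expect_equal(back$params, params, tolerance = 1e-12)
  fx <- tiny_part(cfg)
  p1 <- predict_zero_shot(model, fx$protein$graph, fx$molecules)
  p2 <- predict_zero_shot(back, fx$protein$graph, fx$molecules)
  expect_equal(p1$score, p2$score, tolerance = 1e-12)
})
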