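#' Base-model configuration
#'
#' Architecture and loss weights of the protein-specific base predictor: a
#' protein GCN over the residue contact graph, a molecule GCN over
#' embedded categorical atom features, the weakly supervised subgraph
#' information bottleneck (SIB) that softly assigns residues to a pocket
#' subgraph, and the concatenation classifier. Defaults follow the reference
#' architecture (protein widths 1280-512-256-256-256, molecule widths
#' 256-256-256, lambda1 = lambda2 = 0.05, 20 critic ascent steps at lr 0.01);
#' desk-scale work passes smaller widths.
#'
#' @param protein_widths integer vector of GCN widths, input first
#' @param molecule_embed_dim width of the summed categorical embeddings
#' @param molecule_widths molecule GCN widths, input first (must start at
#'   `molecule_embed_dim`)
#' @param assign_hidden hidden width of the assignment MLP (phi1)
#' @param critic_hidden hidden widths of the Donsker-Varadhan critic (phi2)
#' @param classifier_hidden hidden widths of the classifier MLP
#' @param lambda1 weight of the connectivity loss
#' @param lambda2 weight of the mutual-information proxy loss
#' @param mi_inner_steps critic ascent steps per forward pass
#' @param mi_lr critic ascent learning rate
#' @param sib "sib" (full model), "off" (whole-protein embedding, the SIB-off
#'   ablation) or "random" (random row-stochastic assignment, the random-Z
#'   ablation)
#' @param pooling "mean" or "sum" graph readout for the molecule and
#'   whole-protein embeddings
#' @param sub_pool pocket-subgraph readout: "sum" is the plain row-0 of
#'   \eqn{Z^T H} (its magnitude carries how much of the protein the
#'   molecule-conditioned assignment claims, which is the interaction
#'   signal); "mean" divides by the pocket membership mass
#' @param adjacency_norm "sym" or "raw" GCN propagation operator
#' @return a named list of class `base_config`
#' @export
base_config <- function(protein_widths = c(1280L, 512L, 256L, 256L, 256L),
                        molecule_embed_dim = 256L,
                        molecule_widths = c(256L, 256L, 256L, 256L),
                        assign_hidden = 64L,
                        critic_hidden = c(256L, 128L),
                        classifier_hidden = c(256L, 64L),
                        lambda1 = 0.05, lambda2 = 0.05,
                        mi_inner_steps = 20L, mi_lr = 0.01,
                        sib = "sib", pooling = "mean", sub_pool = "sum",
                        adjacency_norm = "sym") {
  stopifnot(molecule_widths[1] == molecule_embed_dim,
            lambda1 >= 0, lambda2 >= 0, mi_inner_steps >= 0, mi_lr > 0)
  sib <- match.arg(sib, c("sib", "off", "random"))
  structure(list(
    protein_widths = as.integer(protein_widths),
    molecule_embed_dim = as.integer(molecule_embed_dim),
    molecule_widths = as.integer(molecule_widths),
    assign_hidden = as.integer(assign_hidden),
    critic_hidden = as.integer(critic_hidden),
    classifier_hidden = as.integer(classifier_hidden),
    lambda1 = lambda1, lambda2 = lambda2,
    mi_inner_steps = as.integer(mi_inner_steps), mi_lr = mi_lr,
    sib = sib, pooling = match.arg(pooling, c("mean", "sum")),
    sub_pool = match.arg(sub_pool, c("sum", "mean")),
    adjacency_norm = match.arg(adjacency_norm, c("sym", "raw"))
  ), class = "base_config")
}

#' Initialize base-model parameters
#'
#' Draws all weights from the current RNG stream (wrap in
#' [withr::with_seed()] for reproducibility).
#'
#' @param config a [base_config()]
#' @return nested parameter list with groups theta_P, theta_M, phi1, phi2,
#'   theta_cls
#' @export
init_base_params <- function(config) {
  dp <- utils::tail(config$protein_widths, 1L)
  dm <- utils::tail(config$molecule_widths, 1L)
  vs <- feature_vocab_sizes()
  list(
    theta_P = mlp_init(config$protein_widths),
    theta_M = list(
      embed = embed_init(vs$atom, config$molecule_embed_dim),
      layers = mlp_init(config$molecule_widths)
    ),
    phi1 = mlp_init(c(dp + dm, config$assign_hidden, 2L)),
    phi2 = mlp_init(c(2L * dp, config$critic_hidden, 1L)),
    theta_cls = mlp_init(c(dm + dp, config$classifier_hidden, 1L))
  )
}

pool_rows <- function(H, pooling) {
  if (pooling == "sum") colSums(H) else colMeans(H)
}

#' Encode a protein contact graph into residue embeddings
#'
#' @param graph a `protein_graph`
#' @param theta_P protein GCN parameters
#' @param config a [base_config()]
#' @return n x d matrix of residue embeddings
#' @export
encode_protein <- function(graph, theta_P, config) {
  X <- graph$node_features
  if (ncol(X) != config$protein_widths[1]) {
    stop_dimension("protein feature width does not match the first GCN width")
  }
  Ahat <- normalize_adjacency(graph$adjacency, config$adjacency_norm)
  gcn_forward(X, Ahat, theta_P)$H
}

#' Encode a molecule graph into atom embeddings and a pooled embedding
#'
#' @param graph a `molecule_graph`
#' @param theta_M molecule parameters (embedding tables + GCN layers)
#' @param config a [base_config()]
#' @return list with `atom_embeddings` (a x d) and `embedding` (d vector)
#' @export
encode_molecule <- function(graph, theta_M, config) {
  X0 <- embed_forward(graph$node_features, theta_M$embed)
  Ahat <- normalize_adjacency(graph$adjacency, config$adjacency_norm)
  H <- gcn_forward(X0, Ahat, theta_M$layers)$H
  list(atom_embeddings = H, embedding = pool_rows(H, config$pooling))
}

#' Soft pocket assignment matrix
#'
#' A per-node MLP on the concatenation of each residue embedding with the
#' pooled molecule embedding, followed by a row-wise softmax over two logits.
#' Column 1 is the pocket-membership probability.
#'
#' @param protein_nodes n x d residue embeddings
#' @param molecule_embed pooled molecule embedding (d_m vector)
#' @param phi1 assignment MLP parameters
#' @return n x 2 row-stochastic matrix
#' @export
sib_assign <- function(protein_nodes, molecule_embed, phi1) {
  n <- nrow(protein_nodes)
  U <- cbind(protein_nodes,
             matrix(molecule_embed, n, length(molecule_embed), byrow = TRUE))
  if (ncol(U) != nrow(phi1[[1]]$W)) {
    stop_dimension("sib_assign: input width does not match phi1")
  }
  row_softmax(mlp_forward(U, phi1)$out)
}

#' Pocket-subgraph embedding
#'
#' Row 0 of \eqn{Z^T H}: the pocket-membership-weighted sum of residue
#' embeddings.
#'
#' @param Z n x 2 row-stochastic assignment matrix
#' @param protein_nodes n x d residue embeddings
#' @return d vector
#' @export
subgraph_embedding <- function(Z, protein_nodes) {
  if (nrow(Z) != nrow(protein_nodes) || ncol(Z) != 2L) {
    stop_dimension("Z must be n x 2 with n matching protein_nodes")
  }
  drop(crossprod(Z[, 1L, drop = FALSE], protein_nodes))
}

#' Connectivity loss of an assignment matrix
#'
#' Mean squared deviation of the diagonal of the row-normalized
#' \eqn{Z^T A Z} from the identity: small when each soft part keeps its edge
#' mass internal, i.e. when Z is a hard assignment into internally connected
#' parts.
#'
#' @param Z n x 2 row-stochastic matrix
#' @param adjacency protein adjacency (0/1, no self-loops)
#' @return nonnegative scalar
#' @export
connectivity_loss <- function(Z, adjacency) {
  conn_loss_grad(Z, adjacency, want_grad = FALSE)$loss
}

conn_loss_grad <- function(Z, adjacency, want_grad = TRUE) {
  eps <- 1e-12
  AZ <- adjacency %*% Z
  S <- crossprod(Z, AZ)                       # 2 x 2
  r <- rowSums(S) + eps
  p <- diag(S) / r
  loss <- mean((p - 1)^2)
  if (!want_grad) return(list(loss = loss))
  dp <- (p - 1)                                # d loss / d p_kk
  G <- matrix(0, 2L, 2L)
  for (k in 1:2) {
    G[k, ] <- -dp[k] * S[k, k] / r[k]^2
    G[k, k] <- G[k, k] + dp[k] / r[k]
  }
  list(loss = loss, dZ = AZ %*% (G + t(G)))
}

#' Binary cross-entropy loss
#'
#' Predictions are clamped to `[eps, 1 - eps]` before taking logs.
#'
#' @param y 0/1 label (or vector)
#' @param yhat predicted probability (or vector)
#' @param eps clamp width
#' @return mean BCE
#' @export
bce_loss <- function(y, yhat, eps = 1e-7) {
  yhat <- pmin(pmax(yhat, eps), 1 - eps)
  mean(-y * log(yhat) - (1 - y) * log(1 - yhat))
}

#' Classify a molecule/pocket embedding pair
#'
#' MLP with terminal sigmoid on the concatenation of the pooled molecule
#' embedding and the pocket-subgraph embedding.
#'
#' @param G_m pooled molecule embedding
#' @param G_sub pocket-subgraph embedding
#' @param theta_cls classifier parameters
#' @return probability in (0, 1)
#' @export
classify <- function(G_m, G_sub, theta_cls) {
  x <- matrix(c(G_m, G_sub), 1L)
  if (ncol(x) != nrow(theta_cls[[1]]$W)) {
    stop_dimension("classify: embedding widths do not match theta_cls")
  }
  sigmoid(drop(mlp_forward(x, theta_cls)$out))
}

# --- Donsker-Varadhan mutual-information proxy -------------------------------

# T matrix, loss and all gradients for the DV bound. whole/sub are N x d
# batches; row order pairs (i, j) i-major.
mi_forward_backward <- function(whole, sub, phi2, want_grads = TRUE) {
  N <- nrow(whole)
  if (N < 2L) stop_validation("mi_proxy_loss needs a batch of at least 2")
  d <- ncol(whole)
  Ri <- whole[rep(seq_len(N), each = N), , drop = FALSE]
  Rj <- sub[rep(seq_len(N), times = N), , drop = FALSE]
  fw <- mlp_forward(cbind(Ri, Rj), phi2)
  Tv <- drop(fw$out)                          # length N^2, r = (i-1)N + j
  diag_idx <- (seq_len(N) - 1L) * N + seq_len(N)
  off <- setdiff(seq_len(N * N), diag_idx)
  m <- max(Tv[off])
  lse <- m + log(sum(exp(Tv[off] - m)))       # log sum_{i != j} e^T
  loss <- mean(Tv[diag_idx]) - (lse - log(N))
  if (!want_grads) return(list(loss = loss))
  dT <- numeric(N * N)
  dT[diag_idx] <- 1 / N
  dT[off] <- -exp(Tv[off] - lse)
  bw <- mlp_backward(matrix(dT, ncol = 1L), phi2, fw$cache)
  grp_i <- rep(seq_len(N), each = N)
  grp_j <- rep(seq_len(N), times = N)
  dwhole <- rowsum(bw$dX[, seq_len(d), drop = FALSE], grp_i, reorder = TRUE)
  dsub <- rowsum(bw$dX[, d + seq_len(d), drop = FALSE], grp_j, reorder = TRUE)
  list(loss = loss, dphi2 = bw$dlayers, dwhole = dwhole, dsub = dsub)
}

#' Mutual-information proxy loss (Donsker-Varadhan bound)
#'
#' \deqn{\frac1N \sum_i T(G_i, G_{sub,i}) -
#'   \log \frac1N \sum_{i \ne j} e^{T(G_i, G_{sub,j})}}
#' with T a dense critic network on the concatenated embeddings. With a
#' constant critic the value is exactly \eqn{-\log(N-1)}.
#'
#' @param whole_embeds N x d batch of whole-graph embeddings
#' @param sub_embeds N x d batch of subgraph embeddings
#' @param phi2 critic parameters
#' @return scalar bound value
#' @export
mi_proxy_loss <- function(whole_embeds, sub_embeds, phi2) {
  mi_forward_backward(as.matrix(whole_embeds), as.matrix(sub_embeds), phi2,
                      want_grads = FALSE)$loss
}

#' Gradient-ascend the critic on the DV bound
#'
#' @param whole_embeds,sub_embeds N x d batches
#' @param phi2 critic parameters
#' @param steps ascent steps
#' @param lr ascent learning rate
#' @return updated phi2
#' @export
mi_critic_ascent <- function(whole_embeds, sub_embeds, phi2, steps, lr) {
  for (s in seq_len(steps)) {
    fb <- mi_forward_backward(whole_embeds, sub_embeds, phi2)
    phi2 <- par_axpy(phi2, lr, fb$dphi2)
  }
  phi2
}

# --- full task loss + analytic gradients -------------------------------------

# a "task part" is list(protein = protein_graph, Ahat (cached), molecules =
# list of molecule_graph, mol_Ahats, labels = numeric 0/1)
prepare_part <- function(protein, molecules, labels, config) {
  list(
    protein = protein,
    Ahat = normalize_adjacency(protein$adjacency, config$adjacency_norm),
    molecules = molecules,
    mol_Ahats = lapply(molecules, function(m) {
      normalize_adjacency(m$adjacency, config$adjacency_norm)
    }),
    labels = as.numeric(labels)
  )
}

# The workhorse: forward pass and (optionally) analytic gradients of
# L = mean BCE + lambda1 * mean connectivity + lambda2 * MI-proxy
# over one protein and a batch of molecules. Gradients cover theta_P,
# theta_M, phi1, theta_cls; phi2 is handled by its inner ascent and returned
# updated (argmax constraint: excluded from the outer descent).
task_loss_grad <- function(params, part, config, want_grad = TRUE) {
  J <- length(part$molecules)
  n <- part$protein$n_residues
  dp <- utils::tail(config$protein_widths, 1L)
  dm <- utils::tail(config$molecule_widths, 1L)
  sib_mode <- config$sib
  pooling <- config$pooling

  pf <- gcn_forward(part$protein$node_features, part$Ahat, params$theta_P)
  H_p <- pf$H
  g_whole <- pool_rows(H_p, pooling)

  mol_fw <- vector("list", J)
  g_m <- matrix(0, J, dm)
  for (j in seq_len(J)) {
    g <- part$molecules[[j]]
    X0 <- embed_forward(g$node_features, params$theta_M$embed)
    fw <- gcn_forward(X0, part$mol_Ahats[[j]], params$theta_M$layers)
    mol_fw[[j]] <- list(X0 = X0, fw = fw)
    g_m[j, ] <- pool_rows(fw$H, pooling)
  }

  # soft assignments, batched over the molecule axis: rows (j-1)*n + i
  Zs <- vector("list", J)
  sib_fw <- NULL
  Zbig <- NULL
  S <- matrix(0, J, dp)
  # pocket readout: row 0 of Z^T H, optionally normalized by the pocket
  # membership mass (sub_pool = "mean")
  sub_mean <- config$sub_pool == "mean"
  zmass <- numeric(J)
  sub_embed_of <- function(Z) {
    u <- drop(crossprod(Z[, 1L, drop = FALSE], H_p))
    if (sub_mean) u / sum(Z[, 1L]) else u
  }
  if (sib_mode == "sib") {
    U <- cbind(H_p[rep(seq_len(n), times = J), , drop = FALSE],
               g_m[rep(seq_len(J), each = n), , drop = FALSE])
    sib_fw <- mlp_forward(U, params$phi1)
    Zbig <- row_softmax(sib_fw$out)
    for (j in seq_len(J)) {
      Zs[[j]] <- Zbig[(j - 1L) * n + seq_len(n), , drop = FALSE]
      zmass[j] <- sum(Zs[[j]][, 1L])
      S[j, ] <- sub_embed_of(Zs[[j]])
    }
  } else if (sib_mode == "random") {
    for (j in seq_len(J)) {
      u <- runif(n)
      Zs[[j]] <- cbind(u, 1 - u)
      zmass[j] <- sum(u)
      S[j, ] <- sub_embed_of(Zs[[j]])
    }
  } else {
    for (j in seq_len(J)) S[j, ] <- g_whole
  }

  cls_in <- cbind(g_m, S)
  cls_fw <- mlp_forward(cls_in, params$theta_cls)
  yhat <- sigmoid(drop(cls_fw$out))
  L_cls <- bce_loss(part$labels, yhat)

  L_conn <- 0
  conn_grads <- NULL
  if (sib_mode != "off" && config$lambda1 > 0) {
    conn_grads <- lapply(Zs, function(Z) {
      conn_loss_grad(Z, part$protein$adjacency, want_grad = want_grad)
    })
    L_conn <- mean(vapply(conn_grads, `[[`, 0, "loss"))
  }

  phi2 <- params$phi2
  L_mi <- 0
  mi <- NULL
  use_mi <- sib_mode != "off" && config$lambda2 > 0 && J >= 2L
  if (use_mi) {
    W_batch <- matrix(g_whole, J, dp, byrow = TRUE)
    if (config$mi_inner_steps > 0L) {
      phi2 <- mi_critic_ascent(W_batch, S, phi2, config$mi_inner_steps,
                               config$mi_lr)
    }
    mi <- mi_forward_backward(W_batch, S, phi2, want_grads = want_grad)
    L_mi <- mi$loss
  }

  loss <- L_cls + config$lambda1 * L_conn + config$lambda2 * L_mi
  aux <- list(
    yhat = yhat, Z = Zs, loss_cls = L_cls, loss_conn = L_conn, loss_mi = L_mi,
    sub_mean = colMeans(S), mol_mean = colMeans(g_m)
  )
  if (!want_grad) {
    return(list(loss = loss, phi2 = phi2, aux = aux))
  }

  # ---- backward -------------------------------------------------------------
  dH_p <- matrix(0, n, dp)
  d_gwhole <- numeric(dp)

  # classifier, batched over molecules
  dz <- matrix((yhat - part$labels) / J, ncol = 1L)
  bw <- mlp_backward(dz, params$theta_cls, cls_fw$cache)
  g_cls <- bw$dlayers
  dG_m <- bw$dX[, seq_len(dm), drop = FALSE]       # J x dm
  dS <- bw$dX[, dm + seq_len(dp), drop = FALSE]    # J x dp

  if (use_mi) {
    dS <- dS + config$lambda2 * mi$dsub
    d_gwhole <- d_gwhole + config$lambda2 * colSums(mi$dwhole)
  }

  g_phi1 <- NULL
  if (sib_mode == "off") {
    d_gwhole <- d_gwhole + colSums(dS)
  } else {
    dZbig <- matrix(0, J * n, 2L)
    for (j in seq_len(J)) {
      rows <- (j - 1L) * n + seq_len(n)
      if (sub_mean) {
        # s = (H^T z) / sum(z): quotient rule
        du <- dS[j, ] / zmass[j]
        dc <- -sum(dS[j, ] * S[j, ]) / zmass[j]
        dH_p <- dH_p + tcrossprod(Zs[[j]][, 1L], du)
        dZbig[rows, 1L] <- H_p %*% du + dc
      } else {
        dH_p <- dH_p + tcrossprod(Zs[[j]][, 1L], dS[j, ])
        dZbig[rows, 1L] <- H_p %*% dS[j, ]
      }
      if (!is.null(conn_grads)) {
        dZbig[rows, ] <- dZbig[rows, ] + (config$lambda1 / J) * conn_grads[[j]]$dZ
      }
    }
    if (sib_mode == "sib") {
      Zall <- do.call(rbind, Zs)
      dlogits <- Zall * (dZbig - rowSums(dZbig * Zall))
      bw1 <- mlp_backward(dlogits, params$phi1, sib_fw$cache)
      g_phi1 <- bw1$dlayers
      dH_p <- dH_p + rowsum(bw1$dX[, seq_len(dp), drop = FALSE],
                            rep(seq_len(n), times = J), reorder = TRUE)
      dG_m <- dG_m + rowsum(bw1$dX[, dp + seq_len(dm), drop = FALSE],
                            rep(seq_len(J), each = n), reorder = TRUE)
    }
  }
  if (is.null(g_phi1)) g_phi1 <- par_zero(params$phi1)

  # molecule GCNs; embedding-table backward batched over all atoms
  g_mlayers <- NULL
  all_dX0 <- vector("list", J)
  for (j in seq_len(J)) {
    a <- part$molecules[[j]]$n_atoms
    dHm <- matrix(dG_m[j, ], a, dm, byrow = TRUE)
    if (pooling == "mean") dHm <- dHm / a
    bwm <- gcn_backward(dHm, part$mol_Ahats[[j]], params$theta_M$layers,
                        mol_fw[[j]]$fw$cache)
    g_mlayers <- if (is.null(g_mlayers)) bwm$dlayers
                 else par_axpy(g_mlayers, 1, bwm$dlayers)
    all_dX0[[j]] <- bwm$dX
  }
  g_embed <- embed_backward(
    do.call(rbind, all_dX0),
    do.call(rbind, lapply(part$molecules, `[[`, "node_features")),
    params$theta_M$embed
  )

  pool_scale <- if (pooling == "mean") 1 / n else 1
  dH_p <- dH_p + matrix(d_gwhole * pool_scale, n, dp, byrow = TRUE)
  bwp <- gcn_backward(dH_p, part$Ahat, params$theta_P, pf$cache)

  list(
    loss = loss,
    grads = list(
      theta_P = bwp$dlayers,
      theta_M = list(embed = g_embed, layers = g_mlayers),
      phi1 = g_phi1,
      theta_cls = g_cls
    ),
    phi2 = phi2,
    aux = aux
  )
}

#' Full base-model forward pass for one protein-molecule pair
#'
#' Encodes both graphs, produces the soft pocket assignment Z and the
#' pocket-subgraph embedding, optionally ascends the critic and assembles
#' \eqn{L_{base} = L_{cls} + \lambda_1 L_{conn} + \lambda_2 L_{MI}}. The
#' mutual-information term needs a batch, so it is computed only when
#' `mi_batch` supplies companion molecules (the training loop always scores a
#' task's molecules jointly).
#'
#' @param protein a `protein_graph`
#' @param molecule a `molecule_graph`
#' @param params base-model parameters from [init_base_params()]
#' @param config a [base_config()]
#' @param label optional 0/1 label; when given, losses are returned
#' @param mi_batch optional list of additional `molecule_graph`s that form
#'   the MI batch together with `molecule`
#' @return list with `yhat`, `Z` (n x 2), and when labelled `loss`,
#'   `loss_cls`, `loss_conn`, `loss_mi`
#' @export
base_forward <- function(protein, molecule, params, config, label = NULL,
                         mi_batch = NULL) {
  mols <- c(list(molecule), mi_batch %||% list())
  cfg <- config
  if (length(mols) < 2L) cfg$lambda2 <- 0
  part <- prepare_part(protein, mols,
                       labels = rep(label %||% 0, length(mols)), cfg)
  res <- task_loss_grad(params, part, cfg, want_grad = FALSE)
  out <- list(yhat = res$aux$yhat[1L], Z = res$aux$Z[[1L]], phi2 = res$phi2)
  if (!is.null(label)) {
    # the classification and connectivity terms are for the focal pair; the
    # MI term is a batch quantity by definition
    out$loss_cls <- bce_loss(label, out$yhat)
    out$loss_conn <- if (!is.null(out$Z) && cfg$lambda1 > 0) {
      connectivity_loss(out$Z, protein$adjacency)
    } else 0
    out$loss_mi <- res$aux$loss_mi
    out$loss <- out$loss_cls + cfg$lambda1 * out$loss_conn +
      cfg$lambda2 * out$loss_mi
  }
  out
}
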