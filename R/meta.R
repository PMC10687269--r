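#' Meta-training configuration
#'
#' MAML++-style settings: number of inner adaptation steps, per-layer
#' per-step learning-rate table initialization (LSLR), multi-step loss
#' weights (annealed from uniform toward the final step), task batch size,
#' cosine-annealed meta learning rate, and the task-adaptive self-attention
#' switch.
#'
#' @param inner_steps inner-loop adaptation steps N
#' @param meta_lr outer (meta) learning rate; annealed with a cosine schedule
#' @param meta_lr_min floor of the cosine schedule
#' @param batch_size tasks per outer step B
#' @param k support examples per class (2-way k-shot)
#' @param m query examples per task
#' @param outer_steps outer optimization steps
#' @param first_order treat inner-loop gradients as constants (first-order
#'   approximation); exact second-order gradients via Hessian-vector products
#'   when FALSE
#' @param attention use task-adaptive self-attention weights over the task
#'   batch (FALSE = uniform weights, the attention-off ablation)
#' @param attention_dim key/value dimension of the attention module
#' @param lslr_init initial value of every (layer, step) learning rate
#' @param upsilon optional fixed multi-step loss weights over the
#'   adaptation trajectory including the unadapted parameters (length
#'   `inner_steps + 1`, nonnegative, summing to 1); default is the annealed
#'   schedule
#' @param upsilon_floor floor of the annealed non-final step weights
#' @param grad_clip global norm bound of the outer gradient
#' @param lslr_max upper clamp of the learned per-layer per-step rates
#' @param optimizer outer optimizer: Adam (the usual choice for stabilizing
#'   this kind of meta-training) or plain gradient descent
#' @param weight_decay optional L2 decay applied to the base parameters at
#'   each outer step
#' @param attention_lr_scale multiplier on the attention-module updates; at
#'   small task batches the learned task weights otherwise collapse onto the
#'   easiest tasks early in training
#' @return named list of class `meta_config`
#' @export
meta_config <- function(inner_steps = 5L, meta_lr = 0.001,
                        meta_lr_min = meta_lr / 10, batch_size = 8L,
                        k = 5L, m = 5L, outer_steps = 100L,
                        first_order = TRUE, attention = TRUE,
                        attention_dim = 32L, lslr_init = 0.01,
                        upsilon = NULL, upsilon_floor = NULL,
                        grad_clip = 10, lslr_max = 0.5,
                        optimizer = c("adam", "sgd"), weight_decay = 0,
                        attention_lr_scale = 0.1) {
  stopifnot(inner_steps >= 1L, meta_lr > 0, batch_size >= 1L, lslr_init > 0)
  if (!is.null(upsilon)) {
    stopifnot(length(upsilon) == inner_steps + 1L, all(upsilon >= 0),
              abs(sum(upsilon) - 1) < 1e-8)
  }
  structure(list(
    inner_steps = as.integer(inner_steps), meta_lr = meta_lr,
    meta_lr_min = meta_lr_min, batch_size = as.integer(batch_size),
    k = as.integer(k), m = as.integer(m),
    outer_steps = as.integer(outer_steps),
    first_order = isTRUE(first_order), attention = isTRUE(attention),
    attention_dim = as.integer(attention_dim), lslr_init = lslr_init,
    upsilon = upsilon,
    upsilon_floor = upsilon_floor %||% (0.03 / (inner_steps + 1)),
    grad_clip = grad_clip, lslr_max = lslr_max,
    optimizer = match.arg(optimizer), weight_decay = weight_decay,
    attention_lr_scale = attention_lr_scale
  ), class = "meta_config")
}

#' Multi-step loss weights at a given point of training
#'
#' One weight per query-loss evaluation point along the adaptation
#' trajectory, INCLUDING the unadapted parameters (steps 0..N), so the
#' returned vector has N + 1 entries. Starts uniform and linearly shifts
#' mass onto the final adaptation step, holding earlier steps at a small
#' floor (the MAML++ multi-step loss annealing). Keeping step 0 in the sum is
#' what makes the meta-initialization itself predictive, i.e. zero-shot
#' capable.
#'
#' @param n_steps inner adaptation steps N
#' @param step,total current and total outer step (controls the anneal)
#' @param floor minimum weight of non-final steps
#' @return weights of length N + 1, nonnegative, summing to 1
#' @export
upsilon_weights <- function(n_steps, step = 1L, total = 1L,
                            floor = 0.03 / (n_steps + 1)) {
  m <- n_steps + 1L
  frac <- if (total <= 1L) 0 else min(1, (step - 1) / (total - 1))
  w <- rep(max(1 / m - frac * (1 / m - floor), floor), m)
  w[m] <- 1 - sum(w[-m])
  w
}

cosine_lr <- function(lr, lr_min, step, total) {
  if (total <= 1L) return(lr)
  lr_min + 0.5 * (lr - lr_min) * (1 + cos(pi * (step - 1) / (total - 1)))
}

# --- parameter group plumbing ------------------------------------------------

# named list of access paths, one per (layer-level) learning-rate group
groups_of <- function(grads) {
  out <- list()
  for (nm in names(grads)) {
    sub <- grads[[nm]]
    if (nm == "theta_P") {
      for (l in seq_along(sub)) out[[paste0("theta_P.", l)]] <- list("theta_P", l)
    } else if (nm == "theta_M") {
      out[["theta_M.embed"]] <- list("theta_M", "embed")
      for (l in seq_along(sub$layers)) {
        out[[paste0("theta_M.layers.", l)]] <- list("theta_M", "layers", l)
      }
    } else {
      out[[nm]] <- list(nm)
    }
  }
  out
}

path_get <- function(x, path) {
  for (p in path) x <- x[[p]]
  x
}

path_set <- function(x, path, value) {
  if (length(path) == 1L) {
    x[[path[[1L]]]] <- value
    return(x)
  }
  x[[path[[1L]]]] <- path_set(x[[path[[1L]]]], path[-1L], value)
  x
}

#' Learning-rate table for LSLR
#'
#' One learnable learning rate per parameter group (GCN layer, embedding
#' block, assignment MLP, classifier) and inner step.
#'
#' @param group_names rownames (parameter groups)
#' @param inner_steps number of columns
#' @param init initial value
#' @return matrix with dimnames
#' @export
init_lslr <- function(group_names, inner_steps, init = 0.01) {
  matrix(init, length(group_names), inner_steps,
         dimnames = list(group_names, NULL))
}

#' Initialize the full meta-state
#'
#' Base-model parameters plus the attention parameters (W_Q, W_K, W_V and the
#' scalar projection) and the LSLR table.
#'
#' @param config a [base_config()]
#' @param meta a [meta_config()]
#' @return nested parameter list
#' @export
init_meta_params <- function(config, meta = meta_config()) {
  params <- init_base_params(config)
  dp <- utils::tail(config$protein_widths, 1L)
  dm <- utils::tail(config$molecule_widths, 1L)
  dk <- meta$attention_dim
  # w_out starts at zero so the task weights begin uniform and the attention
  # module departs from neutrality only as it learns
  params$attention <- list(
    Wq = glorot(dp + dm, dk), Wk = glorot(dp + dm, dk),
    Wv = glorot(dp + dm, dk), w_out = numeric(dk)
  )
  gn <- names(groups_of(params[c("theta_P", "theta_M", "phi1", "theta_cls")]))
  params$lslr <- init_lslr(gn, meta$inner_steps, meta$lslr_init)
  params
}

# --- task sampling -----------------------------------------------------------

#' Sample a 2-way k-shot m-query task for one protein
#'
#' Support gets exactly k binding and k nonbinding records; the query gets m
#' of the remaining records. Returns NULL (task-skip signal) when the protein
#' lacks enough records of either class.
#'
#' @param records interaction records of a single protein
#' @param k per-class support size
#' @param m query size
#' @param seed optional seed (otherwise the current RNG stream is used)
#' @return list with `support` and `query` record tibbles, or NULL
#' @export
sample_task <- function(records, k = 5L, m = 5L, seed = NULL) {
  draw <- function() {
    records <- dplyr::arrange(records, .data$molecule_id)
    pos <- which(records$label == "binding")
    neg <- which(records$label == "nonbinding")
    if (length(pos) < k || length(neg) < k ||
        nrow(records) < 2L * k + m) {
      return(NULL)
    }
    sup <- c(pos[sample.int(length(pos), k)], neg[sample.int(length(neg), k)])
    rest <- setdiff(seq_len(nrow(records)), sup)
    qry <- rest[sample.int(length(rest), m)]
    list(support = records[sup, , drop = FALSE],
         query = records[qry, , drop = FALSE])
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

prepare_task <- function(task, protein, molecules_by_id, config) {
  part <- function(recs) {
    prepare_part(
      protein,
      molecules_by_id[recs$molecule_id],
      as.numeric(recs$label == "binding"),
      config
    )
  }
  list(support = part(task$support), query = part(task$query),
       protein_id = protein$protein_id)
}

# --- inner loop --------------------------------------------------------------

#' Inner-loop adaptation with per-layer per-step learning rates
#'
#' Performs N gradient steps on the support loss, each parameter group using
#' its own learning rate for that step (LSLR). Returns the full trajectory of
#' parameter sets so multi-step query losses can be evaluated.
#'
#' @param params parameter list (adapted groups are those present in the
#'   gradient returned by the loss)
#' @param support a prepared support part (or arbitrary data for a custom
#'   `loss_grad`)
#' @param lslr learning-rate table (rows = groups, columns = steps; a column
#'   count smaller than `n_steps` reuses the last column)
#' @param n_steps number of adaptation steps
#' @param config a [base_config()] (ignored when `loss_grad` is given)
#' @param loss_grad optional function(params) -> list(loss, grads) replacing
#'   the base-model support loss
#' @return list with `trajectory` (length N+1, initial parameters first),
#'   `support_losses` (length N) and `support_grads`
#' @export
inner_adapt <- function(params, support, lslr, n_steps, config = NULL,
                        loss_grad = NULL) {
  stopifnot(n_steps >= 1L)
  lg <- loss_grad %||% function(p) task_loss_grad(p, support, config)
  traj <- vector("list", n_steps + 1L)
  traj[[1L]] <- params
  losses <- numeric(n_steps)
  sgrads <- vector("list", n_steps)
  cur <- params
  for (i in seq_len(n_steps)) {
    r <- lg(cur)
    if (!is.finite(r$loss)) {
      abort(sprintf("non-finite support loss at inner step %d", i),
            class = "metabind_numeric_error")
    }
    losses[i] <- r$loss
    sgrads[[i]] <- r$grads
    if (!is.null(r$phi2)) cur$phi2 <- r$phi2
    gps <- groups_of(r$grads)
    col <- min(i, ncol(lslr))
    for (g in names(gps)) {
      p <- gps[[g]]
      cur <- path_set(cur, p,
                      par_axpy(path_get(cur, p), -lslr[g, col],
                               path_get(r$grads, p)))
    }
    traj[[i + 1L]] <- cur
  }
  list(trajectory = traj, support_losses = losses, support_grads = sgrads)
}

#' Multi-step query loss
#'
#' \eqn{\sum_{i=0}^{N} \upsilon_i L_{query}(\theta_i)} over the adaptation
#' trajectory, unadapted parameters included: the multi-step loss of the
#' outer objective.
#'
#' @param trajectory list of N + 1 parameter sets from [inner_adapt()]
#'   (initial parameters first)
#' @param query prepared query part (or data for `loss_fn`)
#' @param upsilon step-importance weights, one per trajectory point
#' @param config a [base_config()] (ignored when `loss_fn` is given)
#' @param loss_fn optional function(params) -> scalar loss
#' @return weighted query loss (scalar)
#' @export
multi_step_query_loss <- function(trajectory, query, upsilon, config = NULL,
                                  loss_fn = NULL) {
  n <- length(upsilon)
  if (length(trajectory) != n) {
    stop_dimension("trajectory must have one parameter set per upsilon weight")
  }
  lf <- loss_fn %||%
    function(p) task_loss_grad(p, query, config, want_grad = FALSE)$loss
  sum(upsilon * vapply(seq_len(n), function(i) lf(trajectory[[i]]), 0))
}

# --- task-adaptive self-attention --------------------------------------------

attention_forward_backward <- function(H, att, dL_deta = NULL) {
  dk <- ncol(att$Wq)
  Q <- H %*% att$Wq
  K <- H %*% att$Wk
  V <- H %*% att$Wv
  Sc <- Q %*% t(K) / sqrt(dk)
  P <- row_softmax(Sc)
  Att <- P %*% V
  scores <- drop(Att %*% att$w_out)
  eta <- softmax_vec(scores)
  if (is.null(dL_deta)) return(list(eta = eta))
  dscores <- eta * (dL_deta - sum(dL_deta * eta))
  dAtt <- tcrossprod(dscores, att$w_out)
  dw_out <- drop(crossprod(Att, dscores))
  dP <- dAtt %*% t(V)
  dV <- crossprod(P, dAtt)
  dS <- P * (dP - rowSums(dP * P))
  dQ <- dS %*% K / sqrt(dk)
  dK <- crossprod(dS, Q) / sqrt(dk)
  list(eta = eta, grads = list(
    Wq = crossprod(H, dQ), Wk = crossprod(H, dK), Wv = crossprod(H, dV),
    w_out = dw_out
  ))
}

#' Task-importance weights from self-attention over a task batch
#'
#' Task embeddings attend to each other (scaled dot-product attention); a
#' learnable scalar projection of the attended values is softmaxed across the
#' batch into nonnegative weights summing to 1.
#'
#' @param task_embeds B x d matrix of task embeddings (pooled pocket
#'   embedding concatenated with the mean query molecule embedding)
#' @param attention attention parameters (Wq, Wk, Wv, w_out)
#' @return length-B weight vector
#' @export
task_weights <- function(task_embeds, attention) {
  task_embeds <- as.matrix(task_embeds)
  if (ncol(task_embeds) != nrow(attention$Wq)) {
    stop_dimension("task embedding width does not match attention parameters")
  }
  attention_forward_backward(task_embeds, attention)$eta
}

# --- outer loop --------------------------------------------------------------

hvp_fd <- function(loss_grad_fn, params, v) {
  nv <- par_norm(v)
  if (nv < 1e-12) return(par_zero(v))
  eps <- 1e-4 / nv
  shift <- function(sgn) {
    p <- params
    for (nm in names(v)) {
      p[[nm]] <- par_axpy(p[[nm]], sgn * eps, v[[nm]])
    }
    loss_grad_fn(p)$grads
  }
  par_map2(shift(1), shift(-1), function(a, b) (a - b) / (2 * eps))
}

# L_all, parameter/LSLR/attention gradients over one task batch. Each task is
# list(support=, query=) of prepared parts (or arbitrary data understood by
# loss_grad_fn(params, data)).
meta_objective <- function(params, task_batch, config, meta, upsilon = NULL,
                           loss_grad_fn = NULL) {
  B <- length(task_batch)
  if (B == 0L) stop_validation("task batch must be non-empty")
  N <- meta$inner_steps
  ups <- upsilon %||% meta$upsilon %||% upsilon_weights(N)
  lgf <- loss_grad_fn %||% function(p, part) task_loss_grad(p, part, config)

  task_losses <- numeric(B)
  fo_grads <- vector("list", B)
  lslr_grads <- vector("list", B)
  embeds <- vector("list", B)
  phi2_last <- NULL

  for (b in seq_len(B)) {
    task <- task_batch[[b]]
    ad <- inner_adapt(params, task$support, params$lslr, N,
                      loss_grad = function(p) lgf(p, task$support))
    # query loss and gradient at every trajectory point, theta_0 included
    qres <- lapply(seq_len(N + 1L), function(i) lgf(ad$trajectory[[i]], task$query))
    qlosses <- vapply(qres, `[[`, 0, "loss")
    task_losses[b] <- sum(ups * qlosses)

    gsum <- par_zero(qres[[1L]]$grads)
    if (meta$first_order) {
      for (i in seq_len(N + 1L)) gsum <- par_axpy(gsum, ups[i], qres[[i]]$grads)
    } else {
      # reverse accumulation through the trajectory: v <- (I - lr_i H_i) v
      gps <- groups_of(qres[[1L]]$grads)
      v <- par_zero(qres[[1L]]$grads)
      for (i in rev(seq_len(N))) {
        v <- par_axpy(v, ups[i + 1L], qres[[i + 1L]]$grads)
        hv <- hvp_fd(function(p) lgf(p, task$support), ad$trajectory[[i]], v)
        col <- min(i, ncol(params$lslr))
        for (g in names(gps)) {
          p <- gps[[g]]
          v <- path_set(v, p, par_axpy(path_get(v, p), -params$lslr[g, col],
                                       path_get(hv, p)))
        }
      }
      gsum <- par_axpy(v, ups[1L], qres[[1L]]$grads)
    }
    fo_grads[[b]] <- gsum

    gps <- groups_of(qres[[1L]]$grads)
    lg <- matrix(0, nrow(params$lslr), ncol(params$lslr),
                 dimnames = dimnames(params$lslr))
    for (t in seq_len(N)) {
      col <- min(t, ncol(params$lslr))
      for (g in names(gps)) {
        p <- gps[[g]]
        acc <- 0
        for (i in t:N) {
          acc <- acc - ups[i + 1L] * par_dot(path_get(qres[[i + 1L]]$grads, p),
                                             path_get(ad$support_grads[[t]], p))
        }
        lg[g, col] <- lg[g, col] + acc
      }
    }
    lslr_grads[[b]] <- lg

    aux <- qres[[N + 1L]]$aux
    if (!is.null(aux) && !is.null(aux$sub_mean)) {
      embeds[[b]] <- c(aux$sub_mean, aux$mol_mean)
    }
    if (!is.null(qres[[N + 1L]]$phi2)) phi2_last <- qres[[N + 1L]]$phi2
  }

  use_att <- meta$attention && !is.null(params$attention) &&
    !any(vapply(embeds, is.null, TRUE))
  att_grads <- NULL
  if (use_att) {
    H <- do.call(rbind, embeds)
    ab <- attention_forward_backward(H, params$attention, dL_deta = task_losses)
    eta <- ab$eta
    att_grads <- ab$grads
  } else {
    eta <- rep(1 / B, B)
  }

  total <- par_zero(fo_grads[[1L]])
  for (b in seq_len(B)) total <- par_axpy(total, eta[b], fo_grads[[b]])
  lslr_total <- Reduce(`+`, Map(function(e, g) e * g, eta, lslr_grads))

  list(
    loss = sum(eta * task_losses), grads = total, lslr_grad = lslr_total,
    attention_grad = att_grads, eta = eta, task_losses = task_losses,
    phi2 = phi2_last
  )
}

#' One meta-update over a batch of tasks
#'
#' Adapts each task on its support set (inner loop with LSLR), evaluates the
#' multi-step query losses, weights tasks with the self-attention module,
#' and applies one outer gradient-descent step to the base parameters, the
#' LSLR table, and the attention parameters.
#'
#' @param params meta-state from [init_meta_params()]
#' @param task_batch list of tasks, each `list(support =, query =)` of
#'   prepared parts
#' @param config a [base_config()]
#' @param meta a [meta_config()]
#' @param alpha meta learning rate for this step (default `meta$meta_lr`)
#' @param upsilon multi-step loss weights (default from `meta`)
#' @param loss_grad_fn optional custom loss, function(params, data) ->
#'   list(loss, grads)
#' @param opt_state Adam moment estimates carried across steps (returned as
#'   the "opt_state" attribute)
#' @return updated params, with attributes "diagnostics" (loss, eta, task
#'   losses) and "opt_state"
#' @export
meta_step <- function(params, task_batch, config, meta, alpha = NULL,
                      upsilon = NULL, loss_grad_fn = NULL, opt_state = NULL) {
  alpha <- alpha %||% meta$meta_lr
  obj <- meta_objective(params, task_batch, config, meta, upsilon,
                        loss_grad_fn)
  # one gradient tree over everything the outer loop trains
  gtree <- list(base = obj$grads)
  if (!is.null(params$lslr) && !is.null(obj$lslr_grad)) {
    gtree$lslr <- obj$lslr_grad
  }
  if (!is.null(obj$attention_grad)) gtree$attention <- obj$attention_grad

  # global gradient-norm clipping stabilizes the outer loop
  total_norm <- par_norm(gtree)
  if (is.finite(meta$grad_clip) && total_norm > meta$grad_clip) {
    gtree <- par_map(gtree, function(g) g * (meta$grad_clip / total_norm))
  }

  if (meta$optimizer == "adam") {
    if (is.null(opt_state)) {
      opt_state <- list(t = 0, m = par_zero(gtree), v = par_zero(gtree))
    }
    opt_state$t <- opt_state$t + 1
    opt_state$m <- par_map2(opt_state$m, gtree,
                            function(m, g) 0.9 * m + 0.1 * g)
    opt_state$v <- par_map2(opt_state$v, gtree,
                            function(v, g) 0.999 * v + 0.001 * g^2)
    bc1 <- 1 - 0.9^opt_state$t
    bc2 <- 1 - 0.999^opt_state$t
    upd <- par_map2(opt_state$m, opt_state$v, function(m, v) {
      (m / bc1) / (sqrt(v / bc2) + 1e-8)
    })
  } else {
    upd <- gtree
  }

  gps <- groups_of(upd$base)
  for (g in names(gps)) {
    p <- gps[[g]]
    cur <- path_get(params, p)
    if (meta$weight_decay > 0) {
      cur <- par_map(cur, function(x) x * (1 - alpha * meta$weight_decay))
    }
    params <- path_set(params, p,
                       par_axpy(cur, -alpha, path_get(upd$base, p)))
  }
  if (!is.null(upd$lslr)) {
    params$lslr <- params$lslr - alpha * upd$lslr
    params$lslr[] <- pmin(pmax(params$lslr, 0), meta$lslr_max)
  }
  if (!is.null(upd$attention)) {
    params$attention <- par_axpy(params$attention,
                                 -alpha * meta$attention_lr_scale,
                                 upd$attention)
  }
  if (!is.null(obj$phi2)) params$phi2 <- obj$phi2
  attr(params, "diagnostics") <- obj[c("loss", "eta", "task_losses")]
  attr(params, "opt_state") <- opt_state
  params
}

#' Meta-train a protein-specific DTI model
#'
#' MAML++-style training across protein tasks: every outer step samples a
#' batch of proteins, draws a fresh 2-way k-shot m-query task for each,
#' adapts on the support set, and performs one meta-update from the
#' attention-weighted multi-step query losses. The meta learning rate is
#' cosine-annealed and the multi-step weights anneal toward the final step.
#'
#' @param records interaction record tibble
#' @param proteins named list of `protein_graph` keyed by protein id
#' @param molecules named list of `molecule_graph` keyed by molecule id
#' @param config a [base_config()]
#' @param meta a [meta_config()]
#' @param train_proteins optional restriction of training task proteins
#' @param max_train_proteins optional cap on the number of task proteins
#' @param validation optional record tibble of held-out pairs (typically the
#'   transductive split); every `eval_every` steps the mean per-protein
#'   zero-shot AUROC is computed on it and the best-scoring parameters are
#'   the ones returned (model selection against the drift and instability of
#'   long meta-training runs)
#' @param eval_every validation cadence in outer steps
#' @param seed integer seed for initialization and task sampling
#' @param verbose print one line per outer step
#' @return object of class `metabind_model` (params, config, trace tibble)
#' @export
meta_train <- function(records, proteins, molecules, config, meta,
                       train_proteins = NULL, max_train_proteins = NULL,
                       validation = NULL, eval_every = 25L,
                       seed = 1L, verbose = FALSE) {
  by_protein <- split(records, records$protein_id)
  ids <- names(by_protein)
  if (!is.null(train_proteins)) ids <- intersect(ids, train_proteins)
  eligible <- ids[vapply(ids, function(pid) {
    r <- by_protein[[pid]]
    sum(r$label == "binding") >= meta$k &&
      sum(r$label == "nonbinding") >= meta$k &&
      nrow(r) >= 2L * meta$k + meta$m
  }, TRUE)]
  if (length(eligible) == 0L) stop_validation("no protein has enough records")

  withr::with_seed(seed, {
    if (!is.null(max_train_proteins) &&
        length(eligible) > max_train_proteins) {
      eligible <- sort(eligible)[sample.int(length(eligible),
                                            max_train_proteins)]
    }
    params <- init_meta_params(config, meta)
    opt_state <- NULL
    trace <- vector("list", meta$outer_steps)
    best_params <- NULL
    best_val <- -Inf
    val_eval <- function(p) {
      mod <- structure(list(params = p,
                            config = list(base = config, meta = meta)),
                       class = "metabind_model")
      aucs <- c()
      for (pid in unique(validation$protein_id)) {
        r <- validation[validation$protein_id == pid, , drop = FALSE]
        if (length(unique(r$label)) < 2L || is.null(proteins[[pid]])) next
        pr <- predict_zero_shot(mod, proteins[[pid]], molecules[r$molecule_id])
        aucs <- c(aucs, auroc(r$label, pr$score))
      }
      if (length(aucs)) mean(aucs) else NA_real_
    }
    for (t in seq_len(meta$outer_steps)) {
      alpha <- cosine_lr(meta$meta_lr, meta$meta_lr_min, t, meta$outer_steps)
      ups <- meta$upsilon %||%
        upsilon_weights(meta$inner_steps, t, meta$outer_steps,
                        meta$upsilon_floor)
      pids <- sample(eligible, min(meta$batch_size, length(eligible)))
      batch <- list()
      for (pid in pids) {
        tk <- sample_task(by_protein[[pid]], meta$k, meta$m)
        if (is.null(tk)) next
        batch <- c(batch, list(prepare_task(tk, proteins[[pid]], molecules,
                                            config)))
      }
      if (length(batch) == 0L) next
      params <- meta_step(params, batch, config, meta, alpha = alpha,
                          upsilon = ups, opt_state = opt_state)
      opt_state <- attr(params, "opt_state")
      d <- attr(params, "diagnostics")
      trace[[t]] <- tibble::tibble(
        step = t, loss = d$loss, alpha = alpha,
        tasks = paste(pids, collapse = ","),
        eta = paste(signif(d$eta, 3), collapse = ",")
      )
      if (verbose) {
        message(sprintf("step %4d  L_all %.4f  alpha %.4g  tasks [%s]",
                        t, d$loss, alpha, paste(pids, collapse = " ")))
      }
      if (!is.null(validation) &&
          (t %% eval_every == 0L || t == meta$outer_steps)) {
        v <- val_eval(params)
        trace[[t]]$val_auroc <- v
        if (is.finite(v) && v > best_val) {
          best_val <- v
          best_params <- params
        }
        if (verbose) message(sprintf("step %4d  validation AUROC %.4f", t, v))
      }
    }
    if (!is.null(best_params)) params <- best_params
  })
  structure(
    list(params = params, config = list(base = config, meta = meta),
         trace = dplyr::bind_rows(trace), train_proteins = eligible,
         validation_auroc = if (is.finite(best_val)) best_val else NA_real_),
    class = "metabind_model"
  )
}

#' @export
print.metabind_model <- function(x, ...) {
  cat(sprintf(
    "<metabind_model: %d training proteins, %d outer steps, final L_all %.4f>\n",
    length(x$train_proteins),
    if (is.null(x$trace)) NA_integer_ else nrow(x$trace),
    if (is.null(x$trace) || nrow(x$trace) == 0) NA_real_
    else utils::tail(x$trace$loss, 1)
  ))
  invisible(x)
}

#' Zero-shot prediction for a protein
#'
#' Scores molecules with the meta-learned parameters directly, without any
#' adaptation.
#'
#' @param model a `metabind_model` (or a params list with `$params` absent)
#' @param protein a `protein_graph`
#' @param molecules list of `molecule_graph`
#' @return tibble (protein_id, molecule_id, score) plus the soft assignment
#'   matrices as the "Z" attribute
#' @export
predict_zero_shot <- function(model, protein, molecules) {
  config <- model$config$base
  cfg <- config
  cfg$lambda2 <- 0   # no MI term needed for scoring
  part <- prepare_part(protein, molecules, rep(0, length(molecules)), cfg)
  res <- task_loss_grad(model$params, part, cfg, want_grad = FALSE)
  out <- tibble::tibble(
    protein_id = protein$protein_id,
    molecule_id = vapply(molecules, `[[`, "", "molecule_id"),
    score = res$aux$yhat
  )
  attr(out, "Z") <- res$aux$Z
  out
}

#' Fine-tune the meta-model on a protein's few-shot set
#'
#' Plain gradient descent of the base loss on the fine-tuning records,
#' starting from the meta-learned initialization; the meta parameters are
#' untouched and a protein-specific model is returned.
#'
#' @param model a `metabind_model`
#' @param protein a `protein_graph`
#' @param molecules list of `molecule_graph` (the fine-tune set)
#' @param labels 0/1 labels aligned with `molecules`
#' @param steps gradient steps
#' @param lr learning rate
#' @return a new `metabind_model` with adapted parameters
#' @export
fine_tune <- function(model, protein, molecules, labels, steps = 20L,
                      lr = 0.01) {
  if (length(molecules) == 0L) stop_validation("fine-tune set is empty")
  config <- model$config$base
  part <- prepare_part(protein, molecules, labels, config)
  params <- model$params
  for (s in seq_len(steps)) {
    r <- task_loss_grad(params, part, config)
    if (lr > 0) {
      gps <- groups_of(r$grads)
      for (g in names(gps)) {
        p <- gps[[g]]
        params <- path_set(params, p,
                           par_axpy(path_get(params, p), -lr,
                                    path_get(r$grads, p)))
      }
    }
    params$phi2 <- r$phi2
  }
  structure(
    list(params = params, config = model$config, trace = model$trace,
         train_proteins = model$train_proteins,
         fine_tuned_protein = protein$protein_id),
    class = "metabind_model"
  )
}
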