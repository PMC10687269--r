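# quadratic surrogate used as the analytic inner-loop oracle
quad_loss_grad <- function(target) {
  function(p) list(loss = 0.5 * sum((p$theta - target)^2),
                   grads = list(theta = p$theta - target))
}

test_that("task sampling is balanced, disjoint, and deterministic", {
  rec <- interaction_records(
    rep("P", 18), sprintf("M%02d", 1:18),
    c(rep("binding", 8), rep("nonbinding", 10))
  )
  tk <- sample_task(rec, k = 5L, m = 5L, seed = 2L)
  expect_equal(sum(tk$support$label == "binding"), 5L)
  expect_equal(sum(tk$support$label == "nonbinding"), 5L)
  expect_equal(nrow(tk$query), 5L)
  expect_length(intersect(tk$support$molecule_id, tk$query$molecule_id), 0L)
  expect_identical(tk, sample_task(rec, k = 5L, m = 5L, seed = 2L))

  # protein with exactly k+k+m records: the query is the complement
  rec15 <- rec[1:15, ]
  tk2 <- sample_task(rec15, k = 5L, m = 5L, seed = 1L)
  expect_setequal(c(tk2$support$molecule_id, tk2$query$molecule_id),
                  rec15$molecule_id)

  # insufficient positives -> skip signal
  rec_bad <- interaction_records(
    rep("P", 12), sprintf("M%02d", 1:12),
    c(rep("binding", 3), rep("nonbinding", 9))
  )
  expect_null(sample_task(rec_bad, k = 5L, m = 2L, seed = 1L))
})

test_that("inner adaptation matches the quadratic closed forms", {
  target <- c(1, -2, 3)
  lg <- quad_loss_grad(target)
  params <- list(theta = c(0, 0, 0))
  r <- 0.3
  lslr <- init_lslr("theta", 2L, init = r)

  ad <- inner_adapt(params, NULL, lslr, 1L, loss_grad = lg)
  expect_equal(ad$trajectory[[2]]$theta,
               params$theta - r * (params$theta - target), tolerance = 1e-6)

  ad2 <- inner_adapt(params, NULL, lslr, 2L, loss_grad = lg)
  expect_equal(ad2$trajectory[[3]]$theta,
               target + (1 - r)^2 * (params$theta - target), tolerance = 1e-6)

  # all-zero learning rates: parameters unchanged, identical losses
  ad0 <- inner_adapt(params, NULL, init_lslr("theta", 3L, init = 0) + 0, 3L,
                     loss_grad = lg)
  expect_equal(ad0$trajectory[[4]]$theta, params$theta)
  expect_equal(ad0$support_losses, rep(ad0$support_losses[1], 3))
})

test_that("multi-step query loss weights the trajectory correctly", {
  # hand-set losses via a loss_fn that reads a step marker
  traj <- list(list(s = 1), list(s = 2), list(s = 3))
  losses <- c(1.0, 0.5, 0.25)
  lf <- function(p) losses[p$s]
  expect_equal(
    multi_step_query_loss(traj, NULL, c(0.2, 0.3, 0.5), loss_fn = lf),
    0.2 * 1 + 0.3 * 0.5 + 0.5 * 0.25
  )
  # one-hot on the final step
  expect_equal(multi_step_query_loss(traj, NULL, c(0, 0, 1), loss_fn = lf), 0.25)
  # uniform weights with identical losses return that loss
  lf1 <- function(p) 0.7
  expect_equal(multi_step_query_loss(traj, NULL, rep(1 / 3, 3), loss_fn = lf1),
               0.7)
  expect_error(multi_step_query_loss(traj[1:2], NULL, c(0.2, 0.3, 0.5),
                                     loss_fn = lf),
               class = "metabind_dimension_error")
})

test_that("upsilon schedules are simplex weights drifting to the final step", {
  for (N in c(1L, 3L, 5L)) {
    w0 <- upsilon_weights(N, 1, 100)
    w1 <- upsilon_weights(N, 100, 100)
    expect_length(w0, N + 1L)   # steps 0..N, the unadapted point included
    expect_equal(sum(w0), 1)
    expect_equal(sum(w1), 1)
    expect_true(all(w0 >= 0) && all(w1 >= 0))
    expect_equal(w0, rep(1 / (N + 1), N + 1), tolerance = 1e-12)
    expect_gt(w1[N + 1], 0.9)
  }
})

test_that("task attention weights form a simplex and respect symmetry", {
  att <- withr::with_seed(4, list(
    Wq = glorot(6, 4), Wk = glorot(6, 4), Wv = glorot(6, 4),
    w_out = rnorm(4)
  ))
  # B = 1: trivially (1)
  expect_equal(task_weights(matrix(rnorm(6), 1), att), 1)
  # identical embeddings: uniform
  H <- matrix(rep(rnorm(6), 4), 4, byrow = TRUE)
  expect_equal(task_weights(H, att), rep(0.25, 4), tolerance = 1e-9)

  # random batch: dense-matrix hand computation of the attention stack
  H <- withr::with_seed(5, matrix(rnorm(24), 4, 6))
  eta <- task_weights(H, att)
  Q <- H %*% att$Wq
  K <- H %*% att$Wk
  V <- H %*% att$Wv
  S <- Q %*% t(K) / sqrt(4)
  P <- exp(S - apply(S, 1, max))
  P <- P / rowSums(P)
  sc <- drop(P %*% V %*% att$w_out)
  expect_equal(eta, exp(sc - max(sc)) / sum(exp(sc - max(sc))),
               tolerance = 1e-9)
  expect_equal(sum(eta), 1, tolerance = 1e-6)

  # permutation equivariance in the batch
  perm <- c(3, 1, 4, 2)
  expect_equal(task_weights(H[perm, ], att), eta[perm], tolerance = 1e-9)
})

test_that("meta_step with alpha 0 leaves parameters unchanged", {
  lgf <- function(p, data) quad_loss_grad(data$t)(p)
  tasks <- list(list(support = list(t = c(1, 1)), query = list(t = c(2, 0))))
  p0 <- list(theta = c(0.5, -0.5), lslr = init_lslr("theta", 2L, 0.1))
  meta <- meta_config(inner_steps = 2L, attention = FALSE,
                      upsilon = c(0.2, 0.4, 0.4))
  p1 <- meta_step(p0, tasks, NULL, meta, alpha = 0, loss_grad_fn = lgf)
  expect_equal(p1$theta, p0$theta)
  expect_equal(p1$lslr, p0$lslr)
})

test_that("first-order meta_step reduces to a hand-rolled FOMAML reference", {
  # single task, upsilon one-hot on the last step, uniform eta
  withr::with_seed(11, {
    target_s <- rnorm(10)
    target_q <- rnorm(10)
    theta0 <- rnorm(10)
  })
  lgf <- function(p, data) quad_loss_grad(data$t)(p)
  task <- list(support = list(t = target_s), query = list(t = target_q))
  r <- 0.2
  alpha <- 0.1
  N <- 3L
  p0 <- list(theta = theta0, lslr = init_lslr("theta", N, r))
  meta <- meta_config(inner_steps = N, first_order = TRUE, attention = FALSE,
                      upsilon = c(0, 0, 0, 1), optimizer = "sgd",
                      grad_clip = Inf)
  p1 <- meta_step(p0, list(task), NULL, meta, alpha = alpha,
                  loss_grad_fn = lgf)

  # two-loop reference: adapt, then apply the query gradient at the adapted
  # point to the initial parameters
  th <- theta0
  for (i in seq_len(N)) th <- th - r * (th - target_s)
  ref <- theta0 - alpha * (th - target_q)
  expect_equal(p1$theta, ref, tolerance = 1e-5)
})

test_that("second-order outer gradient matches central finite differences", {
  # nonquadratic per-task loss so the Hessian actually matters
  withr::with_seed(12, {
    tasks <- lapply(1:2, function(i) {
      list(support = list(t = rnorm(4)), query = list(t = rnorm(4)))
    })
    theta0 <- rnorm(4) * 0.5
  })
  lgf <- function(p, data) {
    d <- p$theta - data$t
    list(loss = 0.5 * sum(d^2) + 0.1 * sum(p$theta^4),
         grads = list(theta = d + 0.4 * p$theta^3))
  }
  p0 <- list(theta = theta0, lslr = init_lslr("theta", 2L, 0.1))
  meta <- meta_config(inner_steps = 2L, first_order = FALSE,
                      attention = FALSE, upsilon = c(0.2, 0.3, 0.5))
  obj <- metabind:::meta_objective(p0, tasks, NULL, meta, loss_grad_fn = lgf)
  f <- function(th) {
    metabind:::meta_objective(modifyList(p0, list(theta = th)), tasks, NULL,
                              meta, loss_grad_fn = lgf)$loss
  }
  fd <- fd_grad(function(v) f(v), theta0)
  expect_lt(max(abs(fd - obj$grads$theta)), 1e-4)
})

test_that("zero-shot prediction is deterministic and near 0.5 at init", {
  cfg <- tiny_base_config()
  meta <- meta_config(inner_steps = 2L, attention_dim = 4L)
  fx <- tiny_part(cfg, n_mols = 4L)
  # symmetric init: zero out the classifier head -> logits 0 -> prob 0.5
  params <- withr::with_seed(1, init_meta_params(cfg, meta))
  params$theta_cls <- par_map(params$theta_cls, function(x) x * 0)
  model <- structure(list(params = params,
                          config = list(base = cfg, meta = meta)),
                     class = "metabind_model")
  p1 <- predict_zero_shot(model, fx$protein$graph, fx$molecules)
  expect_equal(p1$score, rep(0.5, 4))
  params2 <- withr::with_seed(1, init_meta_params(cfg, meta))
  model2 <- structure(list(params = params2,
                           config = list(base = cfg, meta = meta)),
                      class = "metabind_model")
  pa <- predict_zero_shot(model2, fx$protein$graph, fx$molecules)
  pb <- predict_zero_shot(model2, fx$protein$graph, fx$molecules)
  expect_identical(pa$score, pb$score)
})

test_that("fine-tuning with zero steps or zero lr equals zero-shot", {
  cfg <- tiny_base_config()
  meta <- meta_config(inner_steps = 2L, attention_dim = 4L)
  fx <- tiny_part(cfg, n_mols = 4L)
  params <- withr::with_seed(2, init_meta_params(cfg, meta))
  model <- structure(list(params = params,
                          config = list(base = cfg, meta = meta)),
                     class = "metabind_model")
  base_pred <- predict_zero_shot(model, fx$protein$graph, fx$molecules)

  ft0 <- fine_tune(model, fx$protein$graph, fx$molecules, c(1, 0, 1, 0),
                   steps = 0L)
  expect_equal(predict_zero_shot(ft0, fx$protein$graph, fx$molecules)$score,
               base_pred$score)
  ftlr0 <- fine_tune(model, fx$protein$graph, fx$molecules, c(1, 0, 1, 0),
                     steps = 5L, lr = 0)
  expect_equal(predict_zero_shot(ftlr0, fx$protein$graph, fx$molecules)$score,
               base_pred$score)
  # and actual fine-tuning moves the predictions
  ft <- fine_tune(model, fx$protein$graph, fx$molecules, c(1, 0, 1, 0),
                  steps = 10L, lr = 0.05)
  expect_false(isTRUE(all.equal(
    predict_zero_shot(ft, fx$protein$graph, fx$molecules)$score,
    base_pred$score
  )))
})

test_that("meta-training on a micro benchmark runs and logs a trace", {
  bench <- make_benchmark(synthetic_spec(
    n_proteins = 6L, n_molecules = 40L, residues_range = c(10L, 14L),
    embed_dim = 8L, families = 3L, mols_per_protein = c(25L, 30L), seed = 5L
  ))
  cfg <- tiny_base_config()
  meta <- meta_config(inner_steps = 2L, meta_lr = 0.05, batch_size = 2L,
                      k = 3L, m = 3L, outer_steps = 6L, attention_dim = 4L)
  model <- meta_train(bench$records, bench$proteins, bench$molecules,
                      cfg, meta, seed = 1L)
  expect_s3_class(model, "metabind_model")
  expect_equal(nrow(model$trace), 6L)
  expect_true(all(is.finite(model$trace$loss)))
  td <- tidy(model)
  expect_named(td, c("step", "loss", "alpha"))
  g <- glance(model)
  expect_equal(g$outer_steps, 6L)
  # determinism of the whole training loop under the seed
  model2 <- meta_train(bench$records, bench$proteins, bench$molecules,
                       cfg, meta, seed = 1L)
  expect_equal(model$params, model2$params, tolerance = 1e-12)
  p <- autoplot(model)
  expect_s3_class(p, "ggplot")
})
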