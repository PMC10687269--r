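# Dense/GCN primitives with hand-written backpropagation. Parameter
# containers are nested named lists of matrices/vectors (see utils.R); every
# backward function returns gradients in the same shape as the parameters it
# differentiates, which is what the meta-learning loops consume.

#' Symmetrically normalized adjacency with self-loops
#'
#' \eqn{\hat A = D^{-1/2}(A + I)D^{-1/2}} in "sym" mode (the standard GCN
#' propagation operator); "raw" mode returns \eqn{A + I} unnormalized.
#'
#' @param adjacency symmetric 0/1 matrix
#' @param mode "sym" or "raw"
#' @return dense propagation matrix
#' @export
normalize_adjacency <- function(adjacency, mode = c("sym", "raw")) {
  mode <- match.arg(mode)
  a <- adjacency + diag(nrow(adjacency))
  if (mode == "raw") return(a)
  dinv <- 1 / sqrt(rowSums(a))
  a * outer(dinv, dinv)
}

#' One graph-convolution layer
#'
#' \eqn{H' = \mathrm{ReLU}(\hat A H W + b)} with \eqn{\hat A} the
#' symmetrically normalized adjacency with self-loops.
#'
#' @param node_embed n x d_in node embedding matrix
#' @param adjacency symmetric 0/1 adjacency (no self-loops)
#' @param W d_in x d_out weight matrix
#' @param b length-d_out bias
#' @param norm adjacency normalization mode
#' @return n x d_out matrix
#' @export
gcn_layer <- function(node_embed, adjacency, W, b, norm = "sym") {
  if (ncol(node_embed) != nrow(W)) {
    stop_dimension(sprintf("gcn_layer: input width %d != weight rows %d",
                           ncol(node_embed), nrow(W)))
  }
  ahat <- normalize_adjacency(adjacency, norm)
  relu(sweep(ahat %*% node_embed %*% W, 2L, b, `+`))
}

# --- stacked GCN with caches ------------------------------------------------

gcn_forward <- function(X, Ahat, layers) {
  H <- X
  cache <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    M <- Ahat %*% H
    pre <- add_bias(M %*% layers[[l]]$W, layers[[l]]$b)
    H <- relu(pre)
    cache[[l]] <- list(M = M, mask = pre > 0)
  }
  list(H = H, cache = cache)
}

# dH: gradient at the top of the stack; returns per-layer W/b grads and the
# gradient wrt the input features
gcn_backward <- function(dH, Ahat, layers, cache) {
  dlayers <- vector("list", length(layers))
  for (l in rev(seq_along(layers))) {
    dpre <- dH * cache[[l]]$mask
    dlayers[[l]] <- list(
      W = crossprod(cache[[l]]$M, dpre),
      b = colSums(dpre)
    )
    dH <- Ahat %*% (dpre %*% t(layers[[l]]$W))
  }
  list(dlayers = dlayers, dX = dH)
}

# --- MLP (ReLU hidden, linear output) ---------------------------------------

mlp_init <- function(widths) {
  lapply(seq_len(length(widths) - 1L), function(l) {
    list(W = glorot(widths[l], widths[l + 1L]), b = numeric(widths[l + 1L]))
  })
}

mlp_forward <- function(X, layers) {
  H <- X
  L <- length(layers)
  cache <- vector("list", L)
  for (l in seq_len(L)) {
    pre <- add_bias(H %*% layers[[l]]$W, layers[[l]]$b)
    cache[[l]] <- list(input = H, mask = if (l < L) pre > 0 else NULL)
    H <- if (l < L) relu(pre) else pre
  }
  list(out = H, cache = cache)
}

mlp_backward <- function(dOut, layers, cache) {
  L <- length(layers)
  dlayers <- vector("list", L)
  dH <- dOut
  for (l in rev(seq_len(L))) {
    dpre <- if (l < L) dH * cache[[l]]$mask else dH
    dlayers[[l]] <- list(
      W = crossprod(cache[[l]]$input, dpre),
      b = colSums(dpre)
    )
    dH <- dpre %*% t(layers[[l]]$W)
  }
  list(dlayers = dlayers, dX = dH)
}

# --- categorical embedding tables -------------------------------------------

embed_init <- function(vocab_sizes, dim, sd = 0.5) {
  lapply(vocab_sizes, function(v) matrix(rnorm(v * dim, sd = sd), v, dim))
}

# codes: n x F integer matrix of 0-based codes; node embedding = sum over
# feature tables
embed_forward <- function(codes, tables) {
  X <- matrix(0, nrow(codes), ncol(tables[[1]]))
  for (f in seq_along(tables)) {
    X <- X + tables[[f]][codes[, f] + 1L, , drop = FALSE]
  }
  X
}

embed_backward <- function(dX, codes, tables) {
  lapply(seq_along(tables), function(f) {
    g <- matrix(0, nrow(tables[[f]]), ncol(tables[[f]]))
    agg <- rowsum(dX, group = codes[, f], reorder = TRUE)
    g[as.integer(rownames(agg)) + 1L, ] <- agg
    g
  })
}
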