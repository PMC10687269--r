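#' @importFrom rlang %||% abort
#' @importFrom stats rnorm runif setNames
NULL

is_param_leaf <- function(x) is.numeric(x)

#' Apply a function to every leaf of a nested parameter list
#'
#' Parameter containers throughout the package are nested named lists whose
#' leaves are numeric matrices or vectors. These helpers implement the small
#' amount of "tensor-tree" algebra the optimizers need.
#'
#' @param p nested list of numerics
#' @param f function applied to each leaf
#' @return nested list of the same shape
#' @keywords internal
par_map <- function(p, f) {
  if (is_param_leaf(p)) return(f(p))
  lapply(p, par_map, f = f)
}

par_map2 <- function(a, b, f) {
  if (is_param_leaf(a)) return(f(a, b))
  out <- vector("list", length(a))
  names(out) <- names(a)
  for (i in seq_along(a)) out[[i]] <- par_map2(a[[i]], b[[i]], f)
  out
}

par_zero <- function(p) par_map(p, function(x) x * 0)

#' dest + a * x over a parameter tree
#' @keywords internal
par_axpy <- function(dest, a, x) par_map2(dest, x, function(d, v) d + a * v)

par_dot <- function(a, b) {
  if (is_param_leaf(a)) return(sum(a * b))
  s <- 0
  for (i in seq_along(a)) s <- s + par_dot(a[[i]], b[[i]])
  s
}

par_norm <- function(a) sqrt(par_dot(a, a))

par_flatten <- function(p) {
  if (is_param_leaf(p)) return(as.numeric(p))
  unlist(lapply(p, par_flatten), use.names = FALSE)
}

par_unflatten <- function(template, v) {
  idx <- 0L
  rec <- function(t) {
    if (is_param_leaf(t)) {
      n <- length(t)
      out <- t
      out[] <- v[(idx + 1L):(idx + n)]
      idx <<- idx + n
      return(out)
    }
    lapply(t, rec)
  }
  out <- rec(template)
  stopifnot(idx == length(v))
  out
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Row-wise softmax of a matrix
#' @keywords internal
row_softmax <- function(x) {
  m <- if (ncol(x) == 2L) pmax(x[, 1L], x[, 2L]) else apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# fast bias broadcast: m + one row of b per matrix row
add_bias <- function(m, b) m + rep(b, each = nrow(m))

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Glorot-uniform weight matrix
#' @keywords internal
glorot <- function(d_in, d_out) {
  lim <- sqrt(6 / (d_in + d_out))
  matrix(runif(d_in * d_out, -lim, lim), d_in, d_out)
}

check_finite_matrix <- function(x, what) {
  if (!all(is.finite(x))) {
    abort(sprintf("non-finite values in %s", what), class = "metabind_validation_error")
  }
  invisible(x)
}

stop_validation <- function(msg) abort(msg, class = "metabind_validation_error")
stop_dimension <- function(msg) abort(msg, class = "metabind_dimension_error")
stop_lookup <- function(msg) abort(msg, class = "metabind_lookup_error")
stop_parse <- function(msg) abort(msg, class = "metabind_parse_error")
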