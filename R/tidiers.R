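#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the training trace of a meta-model
#'
#' One row per outer step with the attention-weighted loss and the annealed
#' meta learning rate.
#'
#' @param x a `metabind_model`
#' @param ... unused
#' @return tibble (step, loss, alpha)
#' @method tidy metabind_model
#' @export
tidy.metabind_model <- function(x, ...) {
  if (is.null(x$trace) || nrow(x$trace) == 0L) {
    return(tibble::tibble(step = integer(), loss = numeric(),
                          alpha = numeric()))
  }
  x$trace[, c("step", "loss", "alpha")]
}

#' One-row summary of a meta-model
#'
#' @param x a `metabind_model`
#' @param ... unused
#' @return tibble with training-set size, steps, and first/final loss
#' @method glance metabind_model
#' @export
glance.metabind_model <- function(x, ...) {
  tr <- x$trace
  tibble::tibble(
    n_train_proteins = length(x$train_proteins),
    outer_steps = if (is.null(tr)) NA_integer_ else nrow(tr),
    inner_steps = x$config$meta$inner_steps,
    first_loss = if (is.null(tr) || !nrow(tr)) NA_real_ else tr$loss[1],
    final_loss = if (is.null(tr) || !nrow(tr)) NA_real_
                 else utils::tail(tr$loss, 1)
  )
}

#' Plot the meta-training loss trace
#'
#' @param object a `metabind_model`
#' @param ... unused
#' @return a ggplot
#' @method autoplot metabind_model
#' @export
autoplot.metabind_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$loss)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         color = "black", linewidth = 0.4) +
    ggplot2::labs(x = "outer step", y = "attention-weighted query loss",
                  title = "Meta-training trace") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-protein AUROC from an evaluation report
#'
#' @param report tibble from [per_protein_report()]
#' @return a ggplot
#' @export
plot_per_protein <- function(report) {
  ggplot2::ggplot(report,
                  ggplot2::aes(x = .data$n_pos + .data$n_neg,
                               y = .data$auroc)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "records per protein", y = "AUROC",
                  title = "Per-protein zero-shot performance") +
    ggplot2::theme_minimal()
}
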