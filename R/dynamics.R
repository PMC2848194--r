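#' Per-gene parameters of the tanh rate model
#'
#' One target gene's expression change per time step is
#' \deqn{\Delta g_i(t+1) = \alpha_i \tanh\big(\sum_j w_{ji} g_j(t) +
#'   \sum_k w'_{ki} F_k(t) - \beta_i\big),}
#' so `alpha` is the (signed) amplitude of the rate of change, `beta` the
#' location at which the tanh crosses zero, and the weights the regulation
#' strengths of gene and factor regulators. Regulators absent from `w` /
#' `w_factor` are structurally zero.
#'
#' @param alpha amplitude (expression-change units per time step).
#' @param beta dimensionless offset of the tanh argument.
#' @param w named numeric vector of gene-regulator weights (may be empty).
#' @param w_factor named numeric vector of factor weights (may be empty).
#' @return An object of class `gene_params`.
#' @examples
#' gene_params(1, 0, w = c(g2 = 0.5))
#' @export
gene_params <- function(alpha, beta, w = numeric(), w_factor = numeric()) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (length(w) && is.null(names(w)))
    stop("'w' must be named by regulator id")
  if (length(w_factor) && is.null(names(w_factor)))
    stop("'w_factor' must be named by factor id")
  structure(list(alpha = alpha, beta = beta, w = w, w_factor = w_factor),
            class = "gene_params")
}

#' @export
print.gene_params <- function(x, ...) {
  cat(sprintf("tanh rate model parameters: alpha = %.4g, beta = %.4g\n",
              x$alpha, x$beta))
  if (length(x$w))
    cat("  gene weights:",
        paste(sprintf("%s = %.4g", names(x$w), x$w), collapse = ", "), "\n")
  if (length(x$w_factor))
    cat("  factor weights:",
        paste(sprintf("%s = %.4g", names(x$w_factor), x$w_factor),
              collapse = ", "), "\n")
  invisible(x)
}

#' One-step expression change under the tanh rate model
#'
#' Deterministic increment \eqn{\Delta g_i(t+1)} given the state at time
#' t. The output is bounded by `|alpha|` for any state (tanh saturation).
#'
#' @param params a [gene_params()] object.
#' @param state named numeric vector supplying the current value of every
#'   regulator named in `params` (genes and factors).
#' @return scalar increment.
#' @examples
#' p <- gene_params(1, 0.5, w = c(g2 = 1))
#' one_step_delta(p, c(g2 = 1))  # tanh(0.5)
#' @export
one_step_delta <- function(params, state) {
  regs <- c(names(params$w), names(params$w_factor))
  missing <- setdiff(regs, names(state))
  if (length(missing))
    stop("state is missing regulator(s): ", paste(missing, collapse = ", "))
  u <- sum(params$w * state[names(params$w)]) +
    sum(params$w_factor * state[names(params$w_factor)]) - params$beta
  params$alpha * tanh(u)
}

# tanh argument u(t) for t = 1..T-1, vectorised over time
tanh_argument <- function(params, data) {
  Tn <- n_time(data)
  u <- rep(-params$beta, Tn - 1L)
  for (r in names(params$w))
    u <- u + params$w[[r]] * data$values[r, seq_len(Tn - 1L)]
  for (r in names(params$w_factor))
    u <- u + params$w_factor[[r]] * data$values[r, seq_len(Tn - 1L)]
  u
}

#' One-step-ahead predicted expression series
#'
#' Predicts \eqn{\hat g_i(t+1) = g_i(t) + \Delta g_i(t+1)} for t = 1..T-1,
#' conditioning each step on the *observed* state at time t (teacher
#' forcing). With `free_running = TRUE` the prediction instead feeds its
#' own output forward from the observed initial value; this variant is
#' offered for inspection but is not used in fitting.
#'
#' @param params a [gene_params()] object.
#' @param data an [expr_ts()] dataset containing the target gene and all
#'   regulators.
#' @param gene target gene id.
#' @param free_running logical; see above.
#' @return numeric vector of length T-1, the predictions for times 2..T.
#' @export
predict_series <- function(params, data, gene, free_running = FALSE) {
  if (!gene %in% rownames(data$values))
    stop("gene not in dataset: ", gene)
  Tn <- n_time(data)
  if (Tn < 2L) stop("need at least two time points")
  regs <- c(names(params$w), names(params$w_factor))
  missing <- setdiff(regs, rownames(data$values))
  if (length(missing))
    stop("dataset is missing regulator(s): ", paste(missing, collapse = ", "))
  if (!free_running)
    return(data$values[gene, seq_len(Tn - 1L)] +
             params$alpha * tanh(tanh_argument(params, data)))
  out <- numeric(Tn - 1L)
  state <- data$values[, 1L]
  for (t in seq_len(Tn - 1L)) {
    state[gene] <- if (t == 1L) data$values[gene, 1L] else out[t - 1L]
    # other rows stay observed: only the target feeds back
    obs <- data$values[, t]
    obs[gene] <- state[gene]
    out[t] <- obs[gene] + one_step_delta(params, obs)
  }
  out
}

#' Sum of squared one-step prediction errors
#'
#' \eqn{SSE(g_i) = \sum_{t=2}^{T} (g_i(t) - \hat g_i(t))^2} with one-step
#' -ahead predictions from [predict_series()].
#'
#' @inheritParams predict_series
#' @return non-negative scalar; 0 iff the fit is perfect.
#' @export
sse_gene <- function(params, data, gene) {
  pred <- predict_series(params, data, gene)
  obs <- data$values[gene, -1L]
  sum((obs - pred)^2)
}

#' Normalised lack-of-fit cost SSE/Var
#'
#' The cost minimised by the annealing optimizer: the one-step SSE of the
#' target gene divided by its unbiased sample variance across time. The
#' normalisation makes costs comparable across genes of different
#' expression scale.
#'
#' @inheritParams predict_series
#' @return non-negative scalar.
#' @export
cost_gene <- function(params, data, gene) {
  v <- data$var[[gene]]
  if (!is.finite(v) || v <= 0)
    stop("gene has zero variance across time: ", gene)
  sse_gene(params, data, gene) / v
}
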