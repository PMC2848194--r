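#' Control parameters of the annealing optimizer
#'
#' The parameter estimator is a simulated annealing whose proposals mix
#' damped steepest-descent steps with annealed Gaussian perturbations
#' (stochastic gradient descent enhanced SA). At temperature t (integer
#' countdown from `t_max` to 1) a proposal is a gradient step
#' \eqn{\theta - \lambda \nabla E} with probability
#' \eqn{1 - P_{grad}(t)}, where \eqn{P_{grad} = 0.2 + 0.3 t/t_{max}},
#' and otherwise a Gaussian move with scale `sigma0 * t / t_max`.
#' Proposals are accepted by the Metropolis-Hastings rule
#' ([mh_accept()]). After `inner_iters` proposals per temperature, the
#' run converges when the energies of `n_c` consecutive temperature
#' pairs differ by less than `eps`; it then restarts from the incumbent
#' best with coordinates multiplied by U(0.75, 1.25) draws, and stops
#' after `n_f` consecutive restarts fail to improve the best energy
#' (`max_restarts` is a hard cap).
#'
#' `sa_control()` gives full-precision defaults; `sa_control_budget()`
#' is the reduced budget used inside structure enumeration, where fits
#' are needed for ranking link sets rather than final precision; and
#' `sa_control_screen()` is the coarsest preset used by the factor
#' screen.
#'
#' @param t_max initial temperature (positive integer).
#' @param inner_iters proposals per temperature.
#' @param lambda gradient-step damping constant.
#' @param kappa Metropolis-Hastings temperature scale.
#' @param sigma0 base scale of the random-proposal branch.
#' @param eps convergence tolerance on per-temperature energies.
#' @param n_c number of consecutive flat temperature pairs required.
#' @param n_f restart patience.
#' @param max_restarts hard cap on restarts.
#' @param polish_iters strict-descent gradient steps (adaptive step
#'   length) appended after the annealing loop; the temperature-zero
#'   limit of the acceptance rule, it tightens the energy floor so that
#'   structures of different size are compared fairly.
#' @return a list of class `sa_control`.
#' @export
sa_control <- function(t_max = 100L, inner_iters = 100L, lambda = 0.1,
                       kappa = 0.01, sigma0 = 0.5, eps = 1e-6, n_c = 5L,
                       n_f = 3L, max_restarts = 30L, polish_iters = 200L) {
  stopifnot(t_max >= n_c + 1, lambda >= 0, kappa > 0, eps > 0,
            inner_iters >= 1, n_f >= 1, max_restarts >= 1, polish_iters >= 0)
  structure(list(t_max = as.integer(t_max),
                 inner_iters = as.integer(inner_iters),
                 lambda = lambda, kappa = kappa, sigma0 = sigma0,
                 eps = eps, n_c = as.integer(n_c), n_f = as.integer(n_f),
                 max_restarts = as.integer(max_restarts),
                 polish_iters = as.integer(polish_iters)),
            class = "sa_control")
}

#' @rdname sa_control
#' @param ... overrides passed on to [sa_control()].
#' @export
sa_control_budget <- function(...) {
  do.call(sa_control, modifyList(list(t_max = 15L, inner_iters = 25L,
                                      n_f = 1L, max_restarts = 4L,
                                      eps = 1e-3, polish_iters = 150L),
                                 list(...)))
}

#' @rdname sa_control
#' @export
sa_control_screen <- function(...) {
  do.call(sa_control, modifyList(list(t_max = 10L, inner_iters = 10L,
                                      n_f = 1L, max_restarts = 3L,
                                      eps = 1e-2, polish_iters = 80L),
                                 list(...)))
}

# Design matrix of regulator series at times 1..T-1 for a target gene.
# regulators: character ids (rows of data).
design_matrix <- function(data, regulators) {
  Tn <- n_time(data)
  m <- t(data$values[regulators, seq_len(Tn - 1L), drop = FALSE])
  colnames(m) <- regulators
  m
}

theta_vec <- function(params, regulators) {
  w <- c(params$w, params$w_factor)
  c(params$alpha, params$beta, unname(w[regulators]))
}

theta_to_params <- function(theta, regulators, factor_ids) {
  w <- stats::setNames(theta[-(1:2)], regulators)
  gene_params(theta[1L], theta[2L],
              w = w[!(regulators %in% factor_ids)],
              w_factor = w[regulators %in% factor_ids])
}

#' Gradient of the normalised cost
#'
#' Analytic partial derivatives of E = SSE/Var with respect to
#' (alpha, beta, active weights), in that order. With u(t) the tanh
#' argument and r(t) the one-step residual:
#' dSSE/dalpha = -2 sum r tanh(u); dSSE/dbeta = +2 sum r alpha sech^2(u);
#' dSSE/dw_j = -2 sum r alpha sech^2(u) g_j(t); all divided by Var.
#' Structurally absent weights have no entry (they stay exactly zero).
#'
#' @param params a [gene_params()] object.
#' @param data an [expr_ts()] dataset.
#' @param gene target gene id.
#' @return numeric vector `(alpha, beta, w...)` of partials.
#' @export
sa_gradient <- function(params, data, gene) {
  regs <- c(names(params$w), names(params$w_factor))
  g <- .cpp_sa_gradient(data$values[gene, ], design_matrix(data, regs),
                        theta_vec(params, regs), data$var[[gene]])
  stats::setNames(g, c("alpha", "beta", regs))
}

#' One annealing proposal
#'
#' Draws r ~ U(0,1) and takes a damped gradient step when
#' `r > 0.2 + 0.3 t / t_max`, otherwise a Gaussian perturbation with
#' per-coordinate scale `sigma0 * t / t_max`. Exposed mainly for
#' inspection; the fitting loop runs in compiled code with identical
#' logic.
#'
#' @param theta parameter vector.
#' @param grad gradient at `theta` (same length).
#' @param t current temperature.
#' @param control an [sa_control()] object.
#' @return list with `theta` (the proposal) and `branch`
#'   (`"gradient"` or `"random"`).
#' @export
sa_propose <- function(theta, grad, t, control = sa_control()) {
  p_grad <- 0.2 + 0.3 * t / control$t_max
  if (runif(1) > p_grad) {
    list(theta = theta - control$lambda * grad, branch = "gradient")
  } else {
    sig <- control$sigma0 * t / control$t_max
    list(theta = theta + sig * rnorm(length(theta)), branch = "random")
  }
}

#' Metropolis-Hastings acceptance rule
#'
#' A downhill move (`e_new < e_old`) is always accepted; an uphill move
#' is accepted with probability `exp((e_old - e_new) / (kappa * t))`. As
#' `kappa * t -> 0` the rule degenerates to strict descent.
#'
#' @param e_old,e_new energies of the current and proposed state.
#' @param t temperature (> 0).
#' @param kappa scale constant.
#' @return logical flag.
#' @export
mh_accept <- function(e_old, e_new, t, kappa = 1) {
  if (t <= 0) stop("temperature must be positive")
  if (e_new < e_old) return(TRUE)
  runif(1) < exp((e_old - e_new) / (kappa * t))
}

#' Fit one gene's parameters by annealing
#'
#' Estimates `(alpha, beta, w...)` for a fixed regulator set by the
#' SGD-enhanced annealing loop (see [sa_control()]), minimising the
#' normalised cost SSE/Var. Fitting one gene never touches another
#' gene's parameters, so fits are order-independent.
#'
#' @param data an [expr_ts()] dataset.
#' @param gene target gene id.
#' @param regulators character vector of regulator ids (genes and/or
#'   factors); include `gene` itself for a self-link.
#' @param control an [sa_control()] object.
#' @return list with `params` ([gene_params()]), `energy` (best
#'   SSE/Var), `sse`, and `restarts`.
#' @export
fit_gene_sa <- function(data, gene, regulators, control = sa_control()) {
  if (!gene %in% rownames(data$values)) stop("gene not in dataset: ", gene)
  bad <- setdiff(regulators, rownames(data$values))
  if (length(bad))
    stop("unknown regulator(s): ", paste(bad, collapse = ", "))
  v <- data$var[[gene]]
  if (!is.finite(v) || v <= 0)
    stop("gene has zero variance across time: ", gene)
  fit <- .cpp_sa_fit(data$values[gene, ], design_matrix(data, regulators),
                     v, unclass(control))
  list(params = theta_to_params(fit$theta, regulators, data$factor_ids),
       energy = fit$energy, sse = fit$energy * v,
       restarts = fit$restarts)
}

# Enumerate-and-fit all regulator sets of one size for one target.
# candidates: character ids; returns the .cpp_sa_enum_fit result plus the
# set list. self = id of the target's own row to toggle, or NULL.
enum_fit_sets <- function(data, gene, candidates, d, self = NULL,
                          control = sa_control_budget()) {
  sets <- enumerate_link_sets(candidates, d)
  Tn <- n_time(data)
  cols <- c(candidates, self)
  X <- design_matrix(data, cols)
  idx_sets <- lapply(sets, function(s) match(s, cols))
  self_col <- if (is.null(self)) 0L else length(cols)
  res <- .cpp_sa_enum_fit(data$values[gene, ], X, idx_sets, self_col,
                          data$var[[gene]], unclass(control))
  res$sets <- sets
  res$cols <- cols
  res
}
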