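#' Infer a gene regulatory network from time-course expression data
#'
#' Fits the tanh rate model to an [expr_ts()] dataset: a genetic
#' algorithm searches network structures encoded as per-gene in-degrees
#' (capped at `l_max`), scoring each structure by AIC or BIC; for every
#' candidate in-degree the regulator sets are enumerated exhaustively and
#' each is fitted by the SGD-enhanced annealing optimizer, retaining the
#' smallest-SSE set. The optional self-link of each gene is fitted both
#' ways and kept when the selection criterion favours it (it is not
#' counted toward the in-degree cap). Designated factor rows act as
#' candidate regulators only and receive no incoming links.
#'
#' @param data an [expr_ts()] dataset (smooth noisy data first with
#'   [mean_filter()]).
#' @param factors optional character vector of factor ids; overrides the
#'   designation carried by `data`. Use [find_factors()] when unknown.
#' @param criterion `"aic"` or `"bic"`.
#' @param l_max per-gene in-degree cap (default 4).
#' @param power_law optional power-law exponent gamma in (2, 3); when
#'   given, initial in-degrees and mutation redraws follow the k^-gamma
#'   law.
#' @param ga a [ga_control()] object.
#' @param sa an [sa_control()] object for the per-link-set fits
#'   (default: the reduced enumeration budget [sa_control_budget()]).
#' @param allow_zero_indegree permit in-degree 0 in the encoding
#'   (enlarges the alphabet to 0..l_max).
#' @param seed optional integer seed governing the whole search.
#' @return An object of class `tanhnet` with components `genes` (per-gene
#'   fits: regulators, self flag, parameters, SSE), `score`, `trace`,
#'   `converged`, plus the call and data dimensions. Methods: `print`,
#'   `summary`, `coef`, `predict`, `fitted`, `residuals`, `simulate`,
#'   `plot`, [as_edge_list()].
#' @examples
#' \donttest{
#' net <- benchmark_grn()
#' d <- simulate(net, seed = 1)
#' fit <- tanhnet(d, l_max = 2, ga = ga_control(N = 10, max_generations = 20),
#'                sa = sa_control_screen(), seed = 1)
#' fit
#' }
#' @export
tanhnet <- function(data, factors = NULL, criterion = c("aic", "bic"),
                    l_max = 4, power_law = NULL, ga = ga_control(),
                    sa = sa_control_budget(), allow_zero_indegree = FALSE,
                    seed = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(data, "expr_ts"), l_max >= 1)
  if (!is.null(factors)) {
    data <- expr_ts(data$values, factors = factors)
  }
  if (!is.null(seed)) set.seed(seed)
  res <- run_ga(data, criterion = criterion, l_max = l_max,
                gamma = power_law, ga = ga, sa = sa,
                allow_zero_indegree = allow_zero_indegree)
  structure(
    c(res,
      list(criterion = criterion, l_max = l_max, power_law = power_law,
           factor_ids = data$factor_ids, gene_ids = data$gene_ids,
           data = data, call = match.call())),
    class = "tanhnet")
}

#' Edge list of a fitted or true network
#'
#' @param x a `tanhnet` fit, a [grn()] network, or a data.frame already
#'   holding columns `regulator`, `target`, `weight`.
#' @return data.frame with columns `regulator`, `target`, `weight`,
#'   ordered by (regulator, target).
#' @export
as_edge_list <- function(x) {
  if (is.data.frame(x)) {
    e <- x[c("regulator", "target", "weight")]
  } else if (inherits(x, "grn")) {
    e <- x$edges
  } else if (inherits(x, "tanhnet_merge")) {
    e <- x$edges
  } else if (inherits(x, "tanhnet")) {
    rows <- lapply(x$genes, function(g) {
      w <- c(g$params$w, g$params$w_factor)
      if (!length(w))
        return(data.frame(regulator = character(), target = character(),
                          weight = numeric()))
      data.frame(regulator = names(w), target = g$gene, weight = unname(w))
    })
    e <- do.call(rbind, rows)
  } else stop("cannot extract an edge list from class ",
              paste(class(x), collapse = "/"))
  e <- e[order(e$regulator, e$target), , drop = FALSE]
  rownames(e) <- NULL
  e
}

#' @export
print.tanhnet <- function(x, ...) {
  cat("Inferred gene network (tanhnet)\n")
  cat(sprintf("  %d genes, %d factors, %d predicted links\n",
              length(x$gene_ids), length(x$factor_ids),
              nrow(as_edge_list(x))))
  cat(sprintf("  criterion: %s%s, score: %.6f, %d generations%s\n",
              toupper(x$criterion),
              if (is.null(x$power_law)) "" else
                sprintf(" (power law, gamma = %.2f)", x$power_law),
              x$score, x$generations,
              if (x$converged) "" else " (budget exhausted)"))
  invisible(x)
}

#' @export
summary.tanhnet <- function(object, ...) {
  per_gene <- data.frame(
    gene = names(object$genes),
    in_degree = vapply(object$genes, function(g) length(g$regulators), 0L),
    self = vapply(object$genes, function(g) g$self, FALSE),
    sse = vapply(object$genes, function(g) g$sse, 0),
    cost = vapply(object$genes, function(g)
      g$sse / object$data$var[[g$gene]], 0),
    row.names = NULL)
  out <- list(per_gene = per_gene, score = object$score,
              criterion = object$criterion,
              converged = object$converged,
              edges = as_edge_list(object))
  class(out) <- "summary.tanhnet"
  out
}

#' @export
print.summary.tanhnet <- function(x, ...) {
  cat(sprintf("Network fit, %s score %.6f (%s)\n", toupper(x$criterion),
              x$score, if (x$converged) "converged" else "not converged"))
  cat("Per-gene fits:\n")
  print(x$per_gene, digits = 4)
  cat(sprintf("%d predicted links\n", nrow(x$edges)))
  invisible(x)
}

#' @export
coef.tanhnet <- function(object, ...) {
  do.call(rbind, lapply(object$genes, function(g) {
    data.frame(gene = g$gene, alpha = g$params$alpha, beta = g$params$beta,
               row.names = NULL)
  }))
}

#' One-step-ahead predictions of a fitted network
#'
#' @param object a `tanhnet` fit.
#' @param newdata optional [expr_ts()] dataset (defaults to the training
#'   data).
#' @param ... unused.
#' @return matrix genes x (T-1) of predictions for times 2..T.
#' @export
predict.tanhnet <- function(object, newdata = NULL, ...) {
  data <- if (is.null(newdata)) object$data else newdata
  out <- t(vapply(object$genes,
                  function(g) predict_series(g$params, data, g$gene),
                  numeric(n_time(data) - 1L)))
  colnames(out) <- colnames(data$values)[-1L]
  out
}

#' @export
fitted.tanhnet <- function(object, ...) predict(object)

#' @export
residuals.tanhnet <- function(object, ...) {
  obs <- object$data$values[object$gene_ids, -1L, drop = FALSE]
  obs - predict(object)
}

#' Simulate replicate datasets from a fitted network
#'
#' Forward-simulates the fitted dynamics from the observed initial
#' values, with optional noise at divisor `snr`, reusing the observed
#' factor rows as the external forcing.
#'
#' @param object a `tanhnet` fit.
#' @param nsim number of replicates.
#' @param seed optional integer seed.
#' @param snr noise divisor (`Inf` = noise free).
#' @param ... unused.
#' @return an [expr_ts()] (or list of them when `nsim > 1`).
#' @export
simulate.tanhnet <- function(object, nsim = 1, seed = NULL, snr = Inf,
                             ...) {
  net <- fit_as_grn(object)
  simulate(net, nsim = nsim, seed = seed, T = n_time(object$data),
           snr = snr)
}

# a tanhnet fit reinterpreted as a generating network; the observed
# factor rows are carried over verbatim via a fitted sinusoid stand-in
fit_as_grn <- function(object) {
  data <- object$data
  e <- as_edge_list(object)
  alpha <- vapply(object$genes, function(g) g$params$alpha, 0)
  beta <- vapply(object$genes, function(g) g$params$beta, 0)
  init <- data$values[object$gene_ids, 1L]
  names(alpha) <- names(beta) <- names(object$genes)
  net <- grn(e, genes = object$gene_ids, factors = object$factor_ids,
             alpha = alpha, beta = beta, init = init,
             factor_spec = if (length(object$factor_ids))
               data.frame(id = object$factor_ids, amplitude = 1,
                          period = n_time(data), phase = 0) else NULL)
  # replace the sinusoid stand-in by the observed factor series
  net$observed_factors <- data$values[object$factor_ids, , drop = FALSE]
  class(net) <- c("grn_fitted", "grn")
  net
}

#' @export
plot.tanhnet <- function(x, which = c("trace", "fit"), genes = NULL, ...) {
  which <- match.arg(which)
  if (which == "trace") {
    graphics::plot(seq_along(x$trace), x$trace, type = "b", pch = 20,
                   xlab = "generation", ylab = paste(toupper(x$criterion),
                                                     "of best structure"),
                   main = "Structure search trace", ...)
  } else {
    genes <- if (is.null(genes)) head(x$gene_ids, 4L) else genes
    pred <- predict(x)
    old <- graphics::par(mfrow = c(length(genes), 1L),
                         mar = c(2, 4, 1, 1))
    on.exit(graphics::par(old))
    for (g in genes) {
      obs <- x$data$values[g, ]
      graphics::plot(seq_along(obs), obs, type = "l", ylab = g, ...)
      graphics::lines(2:length(obs), pred[g, ], col = 2, lty = 2)
    }
  }
  invisible(x)
}
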