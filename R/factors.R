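#' Minimal normalised cost of every row explained from within the network
#'
#' Treats every row (genes and would-be factors alike) as a regulated
#' gene and finds, by exhaustive enumeration of incoming-link sets of
#' size 1..`l_max` fitted with the annealing optimizer, the smallest
#' achievable SSE/Var. Rows that are genuinely driven from outside the
#' network cannot be explained this way and end up with markedly larger
#' minima.
#'
#' @param data an [expr_ts()] dataset (any factor designation it carries
#'   is ignored here: the point is to find the factors).
#' @param l_max in-degree cap for the enumeration.
#' @param control an [sa_control()] object; ranking needs coarse fits
#'   only, so the default is the coarse screen preset.
#' @param max_combos guard: warn when a single row implies more than
#'   this many link-set fits.
#' @return named numeric vector of minimal SSE/Var per row.
#' @export
min_cost_per_gene <- function(data, l_max = 4,
                              control = sa_control_screen(),
                              max_combos = 1e4) {
  rowsq <- rownames(data$values)
  ncand <- length(rowsq) - 1L
  total <- sum(choose(ncand, seq_len(l_max)))
  if (total > max_combos)
    warning("enumerating ", total, " link sets per row; consider a ",
            "smaller l_max")
  out <- vapply(rowsq, function(g) {
    candidates <- setdiff(rowsq, g)
    best <- Inf
    for (d in seq_len(min(l_max, ncand))) {
      # the self-link is offered as a toggle on the retained set, exactly
      # as in the structure search (it does not count toward l_max)
      res <- enum_fit_sets(data, g, candidates, d, self = g,
                           control = control)
      best <- min(best, res$best_energy, na.rm = TRUE)
    }
    best
  }, 0)
  out
}

#' Boxplot-outlier detection of external factors
#'
#' Flags rows whose minimal SSE/Var is an upper boxplot outlier: cost
#' greater than Q3 + 1.5 IQR (Tukey upper fence, linear-interpolation
#' quartiles). Only the upper fence flags — an unusually small cost is a
#' good fit, not evidence of a factor. Invariant under positive
#' rescaling of all costs.
#'
#' @param costs named numeric vector of per-row minimal costs.
#' @param k fence multiplier (1.5 = boxplot convention).
#' @return character vector of flagged ids (possibly empty).
#' @export
detect_factors <- function(costs, k = 1.5) {
  if (length(costs) < 4L)
    stop("need at least 4 rows to define boxplot fences")
  q <- quantile(costs, c(0.25, 0.75), names = FALSE, type = 7)
  fence <- q[2L] + k * (q[2L] - q[1L])
  names(costs)[costs > fence]
}

#' Identify external factors of a network
#'
#' Convenience wrapper: [min_cost_per_gene()] then [detect_factors()].
#'
#' @inheritParams min_cost_per_gene
#' @param k fence multiplier passed to [detect_factors()].
#' @return list with `costs` (per-row minimal SSE/Var) and `factors`
#'   (flagged ids).
#' @examples
#' \donttest{
#' d <- simulate(benchmark_grn(), seed = 1)
#' find_factors(d, l_max = 2)$factors
#' }
#' @export
find_factors <- function(data, l_max = 4, control = sa_control_screen(),
                         k = 1.5) {
  costs <- min_cost_per_gene(data, l_max = l_max, control = control)
  list(costs = costs, factors = detect_factors(costs, k = k))
}
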