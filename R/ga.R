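#' Control parameters of the genetic structure search
#'
#' @param N population size (even).
#' @param max_generations generation cap.
#' @param conv_window number of consecutive generations over which the
#'   best score must be unchanged (within `tol`) to declare convergence.
#' @param tol convergence tolerance on the best score.
#' @param n_mutants number of mutated chromosomes added to the child
#'   pool each generation (default N/2).
#' @return a list of class `ga_control`.
#' @export
ga_control <- function(N = 50L, max_generations = 200L, conv_window = 20L,
                       tol = 1e-6, n_mutants = NULL) {
  N <- as.integer(N)
  if (N %% 2L != 0L || N < 2L) stop("'N' must be even and >= 2")
  if (is.null(n_mutants)) n_mutants <- N %/% 2L
  structure(list(N = N, max_generations = as.integer(max_generations),
                 conv_window = as.integer(conv_window), tol = tol,
                 n_mutants = as.integer(n_mutants)),
            class = "ga_control")
}

#' Size of the structure search space
#'
#' Under the in-degree encoding each of the `n` genes independently
#' chooses an in-degree from 1..`l_max` (or 0..`l_max` when in-degree 0
#' is allowed), so the space has `l_max^n` (resp. `(l_max+1)^n`)
#' structures; 11 genes with cap 4 give 4^11 = 4,194,304.
#'
#' @param n number of genes.
#' @param l_max per-gene in-degree cap.
#' @param allow_zero whether in-degree 0 is part of the alphabet.
#' @return numeric count.
#' @export
search_space_size <- function(n, l_max, allow_zero = FALSE) {
  stopifnot(n >= 1, l_max >= 1)
  (l_max + as.integer(allow_zero))^n
}

#' All candidate regulator sets of a given size
#'
#' @param candidates character vector of candidate regulator ids.
#' @param d set size (0 gives the single empty set).
#' @return list of character vectors, all `choose(length(candidates), d)`
#'   subsets.
#' @export
enumerate_link_sets <- function(candidates, d) {
  if (d > length(candidates))
    stop("in-degree ", d, " exceeds the ", length(candidates),
         " candidates")
  if (d == 0L) return(list(character()))
  if (d == length(candidates)) return(list(candidates))
  m <- combn(candidates, d)
  lapply(seq_len(ncol(m)), function(j) m[, j])
}

#' Power-law in-degree distribution over 1..l_max
#'
#' Normalised probabilities proportional to \eqn{k^{-\gamma}} for
#' k = 1..l_max, the in-degree prior used to restrict the structure
#' search space (2 < gamma < 3 in cellular networks).
#'
#' @param gamma exponent in (2, 3).
#' @param l_max in-degree cap.
#' @return numeric probability vector of length `l_max`.
#' @export
powerlaw_indegree_probs <- function(gamma, l_max) {
  if (gamma <= 2 || gamma >= 3) stop("gamma must be in (2, 3)")
  p <- seq_len(l_max)^(-gamma)
  p / sum(p)
}

# ---- chromosome helpers -------------------------------------------------
# A chromosome is an n x l_max 0/1 integer matrix; the in-degree of gene
# i is the popcount of row i. Factors are not encoded (no in-degree).

chrom_from_degrees <- function(deg, l_max) {
  n <- length(deg)
  m <- matrix(0L, n, l_max)
  for (i in seq_len(n))
    if (deg[i] > 0L) m[i, sample.int(l_max, deg[i])] <- 1L
  m
}

chrom_degrees <- function(chrom) rowSums(chrom)

# re-set one random bit in any all-zero gene row (used when in-degree 0
# is not part of the alphabet)
chrom_repair <- function(chrom, min_degree = 1L) {
  z <- which(rowSums(chrom) < min_degree)
  for (i in z) chrom[i, sample.int(ncol(chrom), 1L)] <- 1L
  chrom
}

#' One-point crossover of two structure chromosomes
#'
#' Chromosomes are flattened gene-block-wise into bit strings; a cut
#' point is drawn uniformly over the interior positions (never the end
#' points) and the suffixes are swapped. The per-position bit sum of the
#' two children equals that of the parents, so total link counts are
#' conserved across the pair.
#'
#' @param p1,p2 chromosomes (equal-dimension 0/1 matrices, genes by
#'   l_max).
#' @return list of two child chromosomes.
#' @export
ga_crossover <- function(p1, p2) {
  stopifnot(all(dim(p1) == dim(p2)))
  L <- length(p1)
  if (L < 3L) stop("chromosome too short for interior crossover")
  v1 <- as.integer(t(p1))
  v2 <- as.integer(t(p2))
  cut <- sample.int(L - 1L, 1L)  # cut after position `cut`, interior only
  tail_idx <- (cut + 1L):L
  c1 <- v1; c2 <- v2
  c1[tail_idx] <- v2[tail_idx]
  c2[tail_idx] <- v1[tail_idx]
  shape <- function(v) matrix(v, nrow = nrow(p1), byrow = TRUE)
  list(shape(c1), shape(c2))
}

#' Mutation with inverse-fitness selection
#'
#' Selects `n` chromosomes (with replacement) with probability
#' proportional to `max(scores) - score + delta` — in this minimisation
#' setting the fitter (lower-scoring) a chromosome, the likelier it is
#' mutated — and toggles exactly one uniformly chosen bit of each
#' selected chromosome. With all scores equal the selection is uniform.
#' When a power-law exponent is supplied, mutation instead redraws one
#' uniformly chosen gene's in-degree from the k^-gamma law.
#'
#' @param population list of chromosomes.
#' @param scores numeric fitness scores (lower = fitter).
#' @param n number of mutants to produce (default: population size).
#' @param gamma optional power-law exponent; see above.
#' @param delta degeneracy guard added to every selection weight.
#' @return list of `n` mutated chromosomes, with the index of the
#'   mutated parent in attribute `"parent"`.
#' @export
ga_mutate <- function(population, scores, n = length(population),
                      gamma = NULL, delta = 1e-9) {
  stopifnot(length(population) == length(scores), all(is.finite(scores)))
  w <- max(scores) - scores + delta
  idx <- sample.int(length(population), n, replace = TRUE, prob = w)
  out <- lapply(idx, function(i) {
    chrom <- population[[i]]
    if (is.null(gamma)) {
      b <- sample.int(length(chrom), 1L)
      chrom[b] <- 1L - chrom[b]
    } else {
      gi <- sample.int(nrow(chrom), 1L)
      d <- sample(seq_len(ncol(chrom)), 1L,
                  prob = powerlaw_indegree_probs(gamma, ncol(chrom)))
      row <- integer(ncol(chrom))
      row[sample.int(ncol(chrom), d)] <- 1L
      chrom[gi, ] <- row
    }
    chrom
  })
  attr(out, "parent") <- idx
  out
}

#' Elitist selection of the next generation
#'
#' Keeps the N/2 fittest parents and the N/2 fittest children (lower
#' score = fitter). Ties break deterministically by (score, fewer total
#' links, position). If fewer than N/2 children are available the
#' shortfall is topped up from the parents.
#'
#' @param parents,children lists of chromosomes.
#' @param parent_scores,child_scores numeric scores.
#' @param N size of the next generation (even).
#' @return list with `population` (length `N`) and `scores`.
#' @export
ga_select_next <- function(parents, children, parent_scores, child_scores,
                           N = length(parents)) {
  stopifnot(N %% 2L == 0L)
  rank_of <- function(pop, scores)
    order(scores, vapply(pop, sum, 0), seq_along(pop))
  half <- N %/% 2L
  po <- rank_of(parents, parent_scores)
  co <- rank_of(children, child_scores)
  n_child <- min(half, length(children))
  n_parent <- N - n_child
  keep_p <- head(po, n_parent)
  keep_c <- head(co, n_child)
  list(population = c(parents[keep_p], children[keep_c]),
       scores = c(parent_scores[keep_p], child_scores[keep_c]))
}

#' Network selection score (AIC / BIC)
#'
#' Model-selection score of a fitted structure: the summed normalised
#' lack of fit plus a complexity penalty,
#' \deqn{AIC = \sum_i SSE_i / Var(g_i) + 2 p(\pi),}
#' with \eqn{p(\pi) = \sum_i (2 + L_i + self_i)} counting amplitude,
#' offset, incoming links and the optional self-link of every gene; BIC
#' replaces the 2 by \eqn{\ln T'} (T' = T-1 fitted transitions). The
#' first term is -2 log-likelihood under Gaussian noise with per-gene
#' variance Var(g_i), the same normalisation as the optimizer's cost, so
#' a structural change is worth keeping only when it removes more than 2
#' (resp. ln T') normalised error units. Lower is better; only
#' differences matter for selection, and two structures with identical
#' SSE differ by exactly 2 (resp. ln T') per extra link.
#'
#' @param sse per-gene sums of squared one-step errors.
#' @param links per-gene in-degrees L(pi_i) (self-links not counted).
#' @param self per-gene 0/1 self-link indicators.
#' @param var per-gene sample variances.
#' @param T_prime number of fitted transitions (T - 1).
#' @param criterion `"aic"` or `"bic"`.
#' @return scalar score.
#' @export
network_score <- function(sse, links, self, var, T_prime,
                          criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  pen <- if (criterion == "aic") 2 else log(T_prime)
  sum(sse / var) + pen * sum(2 + links + self)
}

# ---- the GA engine ------------------------------------------------------

# Memoised per-(gene, in-degree) enumeration fits. Returns a closure
# `cell(gi, d)` giving, for gene index gi at in-degree d, the best
# (smallest-SSE) link set under each self toggle plus the criterion
# contribution of the better toggle.
make_fit_cache <- function(data, targets, l_max, criterion, sa) {
  Tp <- n_time(data) - 1L
  pen <- if (criterion == "aic") 2 else log(Tp)
  cache <- new.env(parent = emptyenv())
  nodes <- rownames(data$values)
  function(gi, d) {
    key <- paste0(gi, ":", d)
    if (!is.null(got <- cache[[key]])) return(got)
    gene <- targets[gi]
    candidates <- setdiff(nodes, gene)
    res <- enum_fit_sets(data, gene, candidates, d, self = gene,
                         control = sa)
    v <- data$var[[gene]]
    sse <- res$best_energy * v
    contrib <- res$best_energy + pen * (2 + d + c(0, 1))
    toggle <- which.min(contrib)  # 1 = no self, 2 = self
    out <- list(
      set = res$sets[[res$best_set[toggle]]],
      self = toggle == 2L,
      theta = if (toggle == 2L) res$best_theta_self else res$best_theta_noself,
      sse = sse[toggle],
      contrib = contrib[toggle])
    cache[[key]] <- out
    out
  }
}

chrom_score <- function(chrom, cell) {
  deg <- chrom_degrees(chrom)
  sum(vapply(seq_along(deg), function(gi) cell(gi, deg[gi])$contrib, 0))
}

# Genetic-algorithm structure search. `data` must already carry the
# factor designation; targets are the non-factor rows.
run_ga <- function(data, criterion = "aic", l_max = 4, gamma = NULL,
                   ga = ga_control(), sa = sa_control_budget(),
                   allow_zero_indegree = FALSE) {
  targets <- data$gene_ids
  n <- length(targets)
  cell <- make_fit_cache(data, targets, l_max, criterion, sa)
  d_min <- if (allow_zero_indegree) 0L else 1L
  deg_probs <- if (is.null(gamma)) {
    rep(1 / (l_max - d_min + 1L), l_max - d_min + 1L)
  } else powerlaw_indegree_probs(gamma, l_max)
  draw_degree <- function(k) {
    opts <- if (is.null(gamma)) d_min:l_max else 1:l_max
    sample(opts, k, replace = TRUE, prob = deg_probs)
  }
  pop <- lapply(seq_len(ga$N),
                function(i) chrom_from_degrees(draw_degree(n), l_max))
  scores <- vapply(pop, chrom_score, 0, cell = cell)
  best_hist <- numeric(0)
  converged <- FALSE
  for (gen in seq_len(ga$max_generations)) {
    # crossover children from N/2 random parent pairs (skipped for
    # degenerate chromosomes too short for an interior cut)
    children <- list()
    if (n * l_max >= 3L) {
      perm <- sample.int(ga$N)
      for (p in seq_len(ga$N %/% 2L)) {
        pair <- ga_crossover(pop[[perm[2 * p - 1L]]], pop[[perm[2 * p]]])
        children <- c(children, pair)
      }
    }
    # mutants, inverse-fitness selected
    children <- c(children, ga_mutate(pop, scores, n = ga$n_mutants,
                                      gamma = gamma))
    if (!allow_zero_indegree)
      children <- lapply(children, chrom_repair)
    child_scores <- vapply(children, chrom_score, 0, cell = cell)
    sel <- ga_select_next(pop, children, scores, child_scores, N = ga$N)
    pop <- sel$population
    scores <- sel$scores
    best_hist <- c(best_hist, min(scores))
    if (length(best_hist) > ga$conv_window &&
        max(abs(diff(tail_n(best_hist, ga$conv_window + 1L)))) < ga$tol) {
      converged <- TRUE
      break
    }
  }
  ord <- order(scores, vapply(pop, sum, 0), seq_along(pop))
  best <- pop[[ord[1L]]]
  deg <- chrom_degrees(best)
  genes_fit <- lapply(seq_len(n), function(gi) {
    cl <- cell(gi, deg[gi])
    regulators <- c(cl$set, if (cl$self) targets[gi])
    list(gene = targets[gi], regulators = cl$set, self = cl$self,
         sse = cl$sse, contrib = cl$contrib,
         params = theta_to_params(cl$theta, regulators, data$factor_ids))
  })
  names(genes_fit) <- targets
  list(genes = genes_fit, score = min(scores), chromosome = best,
       trace = best_hist, converged = converged,
       generations = length(best_hist))
}

tail_n <- function(x, k) x[seq.int(length(x) - k + 1L, length(x))]
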