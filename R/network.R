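#' Directed gene network with tanh dynamics
#'
#' A ground-truth (or generating) network over `n` genes and `K` external
#' factors: a signed, weighted edge list (regulator -> target, targets
#' are genes only; factors have no incoming links), per-gene rate
#' parameters (`alpha`, `beta`), initial values, and a sinusoid
#' specification per factor from which factor series of any length can be
#' generated.
#'
#' @param edges data.frame with columns `regulator`, `target`, `weight`
#'   (may have zero rows).
#' @param genes character vector of gene ids.
#' @param factors character vector of factor ids.
#' @param alpha,beta named numeric vectors over `genes`.
#' @param init named numeric vector of initial values over `genes`.
#' @param factor_spec data.frame with columns `id`, `amplitude`, `period`,
#'   `phase`, one row per factor.
#' @return An object of class `grn`.
#' @seealso [benchmark_grn()], [random_grn()], [simulate.grn()]
#' @export
grn <- function(edges, genes, factors = character(), alpha, beta, init,
                factor_spec = NULL) {
  edges <- as.data.frame(edges)
  need <- c("regulator", "target", "weight")
  if (!all(need %in% names(edges)))
    stop("edges must have columns regulator, target, weight")
  nodes <- c(genes, factors)
  bad <- setdiff(unique(c(edges$regulator, edges$target)), nodes)
  if (length(bad))
    stop("edge references unknown node: ", paste(bad, collapse = ", "))
  if (any(edges$target %in% factors))
    stop("factors cannot have incoming links")
  if (anyDuplicated(edges[c("regulator", "target")]))
    stop("duplicate edge")
  for (v in c("alpha", "beta", "init")) {
    x <- get(v)
    if (!all(genes %in% names(x)))
      stop("'", v, "' must be named over all genes")
  }
  if (length(factors)) {
    if (is.null(factor_spec) || !all(factors %in% factor_spec$id))
      stop("factor_spec must cover all factors")
  }
  o <- order(edges$regulator, edges$target)
  edges <- edges[o, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, genes = genes, factors = factors,
                 alpha = alpha[genes], beta = beta[genes],
                 init = init[genes], factor_spec = factor_spec),
            class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat("Directed gene network (grn)\n")
  cat(sprintf("  %d genes, %d factors, %d links (%d candidate pairs)\n",
              length(x$genes), length(x$factors), nrow(x$edges),
              n_candidate_links(x)))
  invisible(x)
}

#' Number of candidate directed links of a network
#'
#' Candidate links are every (regulator in genes or factors) ->
#' (target in genes) pair; gene self-pairs are included by default so an
#' 11-gene, 2-factor network has 13 x 11 = 143 candidates.
#'
#' @param net a [grn()] object.
#' @param include_self include gene self-pairs (default `TRUE`).
#' @return integer count.
#' @export
n_candidate_links <- function(net, include_self = TRUE) {
  n <- length(net$genes)
  k <- length(net$factors)
  (n + k) * n - if (include_self) 0L else n
}

#' In-degree of every node of a network
#'
#' @param net a [grn()] object.
#' @param count_self whether self-links count (default `TRUE`).
#' @return named integer vector over genes then factors (factors are 0 by
#'   construction).
#' @export
in_degrees <- function(net, count_self = TRUE) {
  e <- net$edges
  if (!count_self) e <- e[e$regulator != e$target, , drop = FALSE]
  out <- table(factor(e$target, levels = c(net$genes, net$factors)))
  stats::setNames(as.integer(out), names(out))
}

#' Read / write a network edge list as TSV
#'
#' Columns: `regulator`, `target`, `weight`, `sign`; rows ordered
#' lexicographically by (regulator, target). `sign` is redundant with
#' `weight` on write and ignored on read. Comment lines starting `##` are
#' skipped, so files may carry provenance headers.
#'
#' @param path file path.
#' @return `read_network()`: a data.frame of edges; `write_network()`:
#'   the path, invisibly.
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  if (!length(lines)) stop("empty network file: ", path)
  df <- read.delim(text = paste(lines, collapse = "\n"),
                   stringsAsFactors = FALSE)
  known <- c("regulator", "target", "weight", "sign")
  bad <- setdiff(names(df), known)
  if (length(bad))
    stop("unknown column in network file: ", paste(bad, collapse = ", "))
  if (!all(c("regulator", "target", "weight") %in% names(df)))
    stop("network file needs columns regulator, target, weight")
  df[c("regulator", "target", "weight")]
}

#' @param edges data.frame with columns `regulator`, `target`, `weight`
#'   (e.g. `net$edges` or [as_edge_list()] of a fit).
#' @param header optional provenance lines, written prefixed `## `.
#' @rdname read_network
#' @export
write_network <- function(edges, path, header = NULL) {
  edges <- as.data.frame(edges)[c("regulator", "target", "weight")]
  edges <- edges[order(edges$regulator, edges$target), , drop = FALSE]
  edges$sign <- ifelse(edges$weight >= 0, "+", "-")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("## ", header), con)
  writeLines("regulator\ttarget\tweight\tsign", con)
  if (nrow(edges))
    writeLines(paste(edges$regulator, edges$target,
                     format(edges$weight, digits = 17, trim = TRUE),
                     edges$sign, sep = "\t"), con)
  invisible(path)
}
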