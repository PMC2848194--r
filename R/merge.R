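#' Merge two inferred subnetworks into one network
#'
#' Integrates two fitted subnetworks that share a dataset (and possibly
#' factors). For each target gene of the first network, every gene of
#' the second network is evaluated as an additional incoming link: the
#' augmented regulator set is refitted by the annealing optimizer and
#' the candidate giving the largest decrease in SSE/Var is provisionally
#' added; the addition is kept only when the network's AIC/BIC improves,
#' so complexity is penalised. The procedure is then applied
#' symmetrically to the second network, and repeated for `passes`
#' rounds or until no addition is accepted. In-degrees never exceed
#' `l_max`.
#'
#' @param fit_a,fit_b `tanhnet` fits of the two subnetworks.
#' @param data an [expr_ts()] dataset covering all genes and factors of
#'   both fits.
#' @param criterion `"aic"` or `"bic"`.
#' @param l_max in-degree cap for augmented genes.
#' @param passes maximum number of sweeps over each network.
#' @param control an [sa_control()] for the candidate refits.
#' @return object of class `tanhnet_merge`: `edges` (merged edge list),
#'   `accepted` (data.frame of accepted cross-links), and the updated
#'   per-gene structures.
#' @export
merge_networks <- function(fit_a, fit_b, data,
                           criterion = c("aic", "bic"), l_max = 4,
                           passes = 3, control = sa_control_budget()) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(fit_a, "tanhnet"), inherits(fit_b, "tanhnet"),
            inherits(data, "expr_ts"))
  all_ids <- rownames(data$values)
  need <- union(c(fit_a$gene_ids, fit_a$factor_ids),
                c(fit_b$gene_ids, fit_b$factor_ids))
  if (!all(need %in% all_ids))
    stop("data does not cover both subnetworks: missing ",
         paste(setdiff(need, all_ids), collapse = ", "))
  Tp <- n_time(data) - 1L
  pen <- if (criterion == "aic") 2 else log(Tp)

  as_state <- function(fit) {
    lapply(fit$genes, function(g)
      list(gene = g$gene, regulators = g$regulators, self = g$self,
           sse = g$sse, params = g$params))
  }
  contrib <- function(st) {
    st$sse / data$var[[st$gene]] +
      pen * (2 + length(st$regulators) + st$self)
  }
  refit <- function(st, extra) {
    regs <- c(st$regulators, extra)
    full <- c(regs, if (st$self) st$gene)
    f <- fit_gene_sa(data, st$gene, full, control = control)
    list(gene = st$gene, regulators = regs, self = st$self,
         sse = f$sse, params = f$params)
  }

  accepted <- data.frame(regulator = character(), target = character())
  sweep_in <- function(state, donor_genes) {
    for (pass in seq_len(passes)) {
      any_add <- FALSE
      for (g in names(state)) {
        st <- state[[g]]
        if (length(st$regulators) >= l_max) next
        cands <- setdiff(donor_genes, c(st$regulators, st$gene))
        if (!length(cands)) next
        v <- data$var[[st$gene]]
        trials <- lapply(cands, function(cd) refit(st, cd))
        gain <- st$sse / v - vapply(trials, function(tr) tr$sse / v, 0)
        bestj <- which.max(gain)
        # keep the augmented structure only if the criterion improves
        if (contrib(trials[[bestj]]) < contrib(st)) {
          state[[g]] <- trials[[bestj]]
          accepted <<- rbind(accepted,
                             data.frame(regulator = cands[bestj],
                                        target = st$gene))
          any_add <- TRUE
        }
      }
      if (!any_add) break
    }
    state
  }

  state_a <- sweep_in(as_state(fit_a), fit_b$gene_ids)
  state_b <- sweep_in(as_state(fit_b), fit_a$gene_ids)

  edges_of <- function(state) do.call(rbind, lapply(state, function(st) {
    w <- c(st$params$w, st$params$w_factor)
    if (!length(w))
      return(data.frame(regulator = character(), target = character(),
                        weight = numeric()))
    data.frame(regulator = names(w), target = st$gene, weight = unname(w))
  }))
  edges <- rbind(edges_of(state_a), edges_of(state_b))
  edges <- edges[order(edges$regulator, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, accepted = accepted,
                 genes_a = state_a, genes_b = state_b,
                 criterion = criterion),
            class = "tanhnet_merge")
}

#' @export
print.tanhnet_merge <- function(x, ...) {
  cat("Merged network (tanhnet_merge)\n")
  cat(sprintf("  %d links after merging, %d cross-links accepted\n",
              nrow(x$edges), nrow(x$accepted)))
  invisible(x)
}
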