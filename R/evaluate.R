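#' Score a predicted network against a ground truth
#'
#' Compares edge sets over the candidate universe of every
#' (regulator in genes or factors) -> (target in genes) pair; gene
#' self-pairs are candidates by default (13 regulators x 11 targets =
#' 143 for the packaged benchmark), factors never receive links. Rates:
#' TPR = TP / true links (sensitivity), TNR = TN / true non-links,
#' FPR = FP / true non-links, and the modified false positive rate
#' mFPR = FP / (TP + FP), the fraction of predicted links that are
#' wrong (defined as 0 when nothing is predicted).
#'
#' In sign-aware mode a true link only counts as TP when the predicted
#' weight has the true sign; a true link predicted with the wrong sign
#' is a miss (FN), so `tp + fn` still equals the number of true links
#' and `tn + fp` the number of true non-links.
#'
#' @param truth a [grn()] network (or edge data.frame plus `genes` /
#'   `factors`).
#' @param predicted edge list: a data.frame with columns `regulator`,
#'   `target`, `weight`, or a `tanhnet` fit.
#' @param signed compare interaction signs as well (default `FALSE`).
#' @param include_self keep gene self-pairs in the candidate set.
#' @return object of class `grn_score`: a list with confusion counts
#'   `tp`, `fp`, `tn`, `fn` and rates `tpr`, `tnr`, `fpr`, `mfpr`.
#' @examples
#' net <- benchmark_grn()
#' score_network(net, net$edges)  # perfect: TPR 1, mFPR 0
#' @export
score_network <- function(truth, predicted, signed = FALSE,
                          include_self = TRUE) {
  stopifnot(inherits(truth, "grn"))
  pred <- as_edge_list(predicted)
  nodes <- c(truth$genes, truth$factors)
  bad <- setdiff(unique(c(pred$regulator, pred$target)), nodes)
  if (length(bad))
    stop("predicted edge references unknown node: ",
         paste(bad, collapse = ", "))
  if (any(pred$target %in% truth$factors))
    stop("predicted edge targets a factor")
  cand <- expand.grid(regulator = nodes, target = truth$genes,
                      stringsAsFactors = FALSE)
  if (!include_self)
    cand <- cand[cand$regulator != cand$target, , drop = FALSE]
  key <- function(e) paste(e$regulator, e$target, sep = "\r")
  ck <- key(cand)
  te <- truth$edges
  tk <- key(te)
  pk <- key(pred)
  pk <- pk[pk %in% ck]  # predictions outside the universe impossible here
  is_true <- ck %in% tk
  is_pred <- ck %in% pk
  if (signed) {
    tsign <- sign(te$weight)[match(ck, tk)]
    psign <- sign(pred$weight)[match(ck, key(pred))]
    good_sign <- !is.na(tsign) & !is.na(psign) & tsign == psign
    tp <- sum(is_true & is_pred & good_sign)
  } else {
    tp <- sum(is_true & is_pred)
  }
  fn <- sum(is_true) - tp
  fp <- sum(!is_true & is_pred)
  tn <- sum(!is_true) - fp
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn, signed = signed,
    n_candidates = nrow(cand),
    tpr = tp / max(tp + fn, 1L),
    tnr = tn / max(tn + fp, 1L),
    fpr = fp / max(tn + fp, 1L),
    mfpr = if (tp + fp > 0L) fp / (tp + fp) else 0),
    class = "grn_score")
}

#' @export
print.grn_score <- function(x, ...) {
  cat(sprintf("Network score (%s, %d candidate links)\n",
              if (x$signed) "sign-aware" else "unsigned", x$n_candidates))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  TPR %.4f  TNR %.4f  FPR %.4f  mFPR %.4f\n",
              x$tpr, x$tnr, x$fpr, x$mfpr))
  invisible(x)
}

#' Modified true positive rate against a validated regulator list
#'
#' \eqn{mTPR^* = TP / \min(\#validated, \#predicted)}: the true
#' positives relative to the best achievable given how many regulators
#' are validated and how many links were predicted. Defined as 0 when
#' the minimum is 0.
#'
#' @param n_tp number of predicted links confirmed by the validated
#'   list.
#' @param n_validated number of validated regulators.
#' @param n_predicted total number of predicted links (>= `n_tp`).
#' @return rate in `[0, 1]`.
#' @examples
#' mtpr_star(6, 8, 10)  # 0.75
#' @export
mtpr_star <- function(n_tp, n_validated, n_predicted) {
  if (any(c(n_tp, n_validated, n_predicted) < 0))
    stop("counts must be non-negative")
  if (n_predicted < n_tp)
    stop("n_predicted must be at least n_tp")
  m <- min(n_validated, n_predicted)
  if (m == 0) 0 else n_tp / m
}
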