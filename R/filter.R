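#' Mean-filter smoothing of time courses
#'
#' Replaces each point of a series with the average of a centred window
#' of odd width (a 1-by-c mean filter). Windows shrink at the series
#' boundaries, averaging only over available points, so no data are
#' fabricated at the ends and output length equals input length.
#' Applied to an [expr_ts()] dataset the filter runs independently over
#' every row (genes and factors alike) and the per-row variances are
#' recomputed. Conventional widths: 3 for medium-noise (SNR10) data, 5
#' for high-noise (SNR4) data.
#'
#' @param x numeric vector or [expr_ts()] dataset.
#' @param width odd integer window length (1 leaves the input unchanged).
#' @return object of the same type as `x`.
#' @examples
#' mean_filter(c(1, 2, 3, 4, 5), 3)  # 1.5 2 3 4 4.5
#' @export
mean_filter <- function(x, width = 3) {
  if (width %% 2 == 0 || width < 1)
    stop("'width' must be an odd integer >= 1")
  if (inherits(x, "expr_ts")) {
    m <- t(apply(x$values, 1L, mean_filter, width = width))
    dimnames(m) <- dimnames(x$values)
    return(expr_ts(m, factors = x$factor_ids))
  }
  n <- length(x)
  h <- (width - 1L) %/% 2L
  # cumulative-sum window means with shrinking edges
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
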