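#' Time-course expression dataset
#'
#' Container for a genes-by-time expression matrix (log-ratio scale) with
#' a designated set of external factor rows. Factors are nodes that
#' regulate genes inside the network but receive no incoming links from
#' within it. Per-row unbiased sample variances across time are
#' precomputed, as they normalise the model's lack-of-fit cost.
#'
#' @param values numeric matrix, rows = genes and factors, columns = time
#'   points (at least 3). Row names are used as identifiers; unnamed rows
#'   are labelled `g1..gn`.
#' @param factors character vector of row names to treat as external
#'   factors (may be empty).
#' @return An object of class `expr_ts`: a list with elements `values`,
#'   `gene_ids`, `factor_ids` and `var` (per-row variance).
#' @examples
#' m <- rbind(g1 = sin(1:10), g2 = cos(1:10), F1 = sin(1:10 / 2))
#' d <- expr_ts(m, factors = "F1")
#' d
#' @export
expr_ts <- function(values, factors = character()) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (ncol(values) < 3L)
    stop("need at least 3 time points, got ", ncol(values))
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite and non-missing")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  ids <- rownames(values)
  if (anyDuplicated(ids))
    stop("duplicate row id: ", ids[duplicated(ids)][1L])
  factors <- as.character(factors)
  missing <- setdiff(factors, ids)
  if (length(missing))
    stop("factor rows not present in the matrix: ",
         paste(missing, collapse = ", "))
  gene_ids <- setdiff(ids, factors)
  if (length(factors) > length(gene_ids))
    stop("more factors than genes")
  v <- apply(values, 1L, var)  # unbiased, denominator T-1
  structure(
    list(values = values, gene_ids = gene_ids, factor_ids = factors,
         var = v),
    class = "expr_ts")
}

#' @export
print.expr_ts <- function(x, ...) {
  cat("Time-course expression dataset (expr_ts)\n")
  cat(sprintf("  %d genes, %d factors, %d time points\n",
              length(x$gene_ids), length(x$factor_ids), ncol(x$values)))
  if (length(x$factor_ids))
    cat("  factors:", paste(x$factor_ids, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_ts <- function(x) dim(x$values)

n_time <- function(data) ncol(data$values)

#' Read a time-course expression matrix from TSV
#'
#' Expected layout: a header row of time labels, first column the row id.
#' Factor rows are flagged with a `#factor:` prefix on the id, or via the
#' `factors` argument (a character vector or a path to a one-id-per-line
#' file). Comment lines starting `##` are ignored.
#'
#' @param path file path.
#' @param factors optional factor ids or a sidecar file of ids.
#' @return An [expr_ts()] object.
#' @export
read_expr_ts <- function(path, factors = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  if (length(lines) < 2L) stop("file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nf[1L]))
    stop("ragged row at line ", which(nf != nf[1L])[1L] + 1L, " in ", path)
  ids <- vapply(fields[-1L], `[[`, "", 1L)
  flagged <- startsWith(ids, "#factor:")
  ids <- sub("^#factor:", "", ids)
  num <- lapply(seq_along(fields[-1L]), function(i) {
    vals <- suppressWarnings(as.numeric(fields[[i + 1L]][-1L]))
    if (anyNA(vals))
      stop("non-numeric cell at line ", i + 1L, " in ", path)
    vals
  })
  m <- do.call(rbind, num)
  rownames(m) <- ids
  colnames(m) <- fields[[1L]][-1L]
  fac <- ids[flagged]
  if (!is.null(factors)) {
    if (length(factors) == 1L && file.exists(factors))
      factors <- readLines(factors)
    fac <- union(fac, factors)
  }
  expr_ts(m, factors = fac)
}

#' Write a time-course expression matrix to TSV
#'
#' Inverse of [read_expr_ts()]: factor rows get a `#factor:` id prefix so
#' the round trip is lossless. An optional provenance header (lines
#' starting `##`) can be prepended.
#'
#' @param data an [expr_ts()] object.
#' @param path output file path.
#' @param header optional character vector of provenance lines (written
#'   prefixed with `## `).
#' @export
write_expr_ts <- function(data, path, header = NULL) {
  ids <- rownames(data$values)
  ids[ids %in% data$factor_ids] <-
    paste0("#factor:", ids[ids %in% data$factor_ids])
  tl <- colnames(data$values)
  if (is.null(tl)) tl <- paste0("t", seq_len(ncol(data$values)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("## ", header), con)
  writeLines(paste(c("id", tl), collapse = "\t"), con)
  for (i in seq_len(nrow(data$values)))
    writeLines(paste(c(ids[i], format(data$values[i, ], digits = 17,
                                      scientific = TRUE, trim = TRUE)),
                     collapse = "\t"), con)
  invisible(path)
}
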