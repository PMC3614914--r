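#' Expression time-course container
#'
#' Bundles an n genes x q time points matrix of real-valued expression with
#' the shared time grid. All series must be sampled on the same grid; by
#' default every row is normalised to mean 0, standard deviation 1 across
#' time points, which is the scale the GP model assumes.
#'
#' @param values numeric matrix, one row per gene, one column per time point.
#' @param times strictly increasing numeric vector of length `ncol(values)`.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   `rownames(values)` or `gene1..geneN`.
#' @param normalise logical; standardise each row (default `TRUE`).
#' @return An object of class `ts_expr`: a list with elements `values`
#'   (matrix with gene ids as rownames), `times`, and `gene_ids`.
#' @examples
#' x <- ts_expr(matrix(rnorm(20), 4, 5), times = 0:4)
#' rowMeans(x$values)  # ~0 after normalisation
#' @export
ts_expr <- function(values, times, gene_ids = NULL, normalise = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  times <- as.numeric(times)
  validate_time_grid(times)
  if (ncol(values) != length(times))
    stop("ncol(values) must equal length(times)")
  if (nrow(values) < 1L) stop("need at least one gene")
  if (anyNA(values)) stop("missing values are not supported")
  if (is.null(gene_ids)) gene_ids <- rownames(values)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(values)))
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length must match nrow(values)")
  if (normalise) values <- normalise_rows(values)
  rownames(values) <- gene_ids
  structure(list(values = values, times = times, gene_ids = gene_ids),
            class = "ts_expr")
}

validate_time_grid <- function(times) {
  if (length(times) < 1L || anyNA(times) || !is.numeric(times))
    stop("time grid must be numeric and non-empty")
  if (anyDuplicated(times)) stop("duplicate time values in grid")
  if (is.unsorted(times, strictly = TRUE))
    stop("time grid must be strictly increasing")
  invisible(times)
}

#' Standardise expression rows
#'
#' Centres and scales each row to mean 0 and standard deviation 1 (sample
#' standard deviation, denominator n - 1). Constant rows cannot be scaled and
#' raise an error naming the offending row.
#'
#' @param values numeric matrix.
#' @return matrix of the same shape.
#' @export
normalise_rows <- function(values) {
  mu <- rowMeans(values)
  centred <- values - mu
  s <- sqrt(rowSums(centred^2) / (ncol(values) - 1L))
  bad <- which(s <= 0 | !is.finite(s))
  if (length(bad))
    stop("constant row(s) cannot be normalised: row ", bad[1L])
  centred / s
}

#' @export
print.ts_expr <- function(x, ...) {
  cat(sprintf("ts_expr: %d genes x %d time points (t in [%g, %g])\n",
              nrow(x$values), length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
dim.ts_expr <- function(x) dim(x$values)

# row subset preserving the grid
expr_subset <- function(x, idx) {
  x$values <- x$values[idx, , drop = FALSE]
  x$gene_ids <- x$gene_ids[idx]
  x
}
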