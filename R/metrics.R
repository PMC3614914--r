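#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement computed from the contingency table:
#' ARI = (sum_ij C(n_ij,2) - E) / (M - E), with
#' E = sum_i C(a_i,2) sum_j C(b_j,2) / C(n,2) and
#' M = (sum_i C(a_i,2) + sum_j C(b_j,2)) / 2. Equals 1 for identical
#' partitions and 0 in expectation under chance; the degenerate case M = E
#' (both partitions trivial) returns 0 by convention.
#'
#' @param p1,p2 partitions: vectors of cluster labels. When both are named,
#'   they must cover the same gene set and are aligned by name; otherwise
#'   they are compared positionally and must have equal length.
#' @return scalar ARI (at most 1).
#' @export
adjusted_rand_index <- function(p1, p2) {
  if (!is.null(names(p1)) && !is.null(names(p2))) {
    if (!setequal(names(p1), names(p2)))
      stop("partitions cover different gene sets")
    p2 <- p2[names(p1)]
  } else if (length(p1) != length(p2)) {
    stop("partitions have different lengths")
  }
  n <- length(p1)
  tab <- table(p1, p2)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  E <- a * b / choose(n, 2)
  M <- (a + b) / 2
  if (abs(M - E) < .Machine$double.eps * max(1, M)) return(0)
  (sum_ij - E) / (M - E)
}

#' Biological homogeneity index of a partition
#'
#' For each cluster containing at least two annotated genes, the fraction of
#' ordered pairs of distinct annotated genes that share at least one
#' annotation term; the BHI is the unweighted average of these fractions
#' over scorable clusters. Genes without annotation are excluded from pair
#' counts. Lies in [0, 1]; higher means more biologically homogeneous
#' clusters relative to the annotation.
#'
#' @param p named partition (cluster label per gene id).
#' @param annotation named list mapping gene id -> character vector of terms
#'   (genes may be absent or have empty term sets: both count as
#'   unannotated).
#' @return scalar BHI in [0, 1].
#' @export
biological_homogeneity_index <- function(p, annotation) {
  if (is.null(names(p))) stop("partition must be named by gene id")
  extra <- setdiff(names(annotation), names(p))
  if (length(extra))
    stop("annotation contains genes absent from the partition: ",
         paste(head(extra, 3L), collapse = ", "))
  per_cluster <- tapply(names(p), p, function(ids) {
    ann <- annotation[intersect(ids, names(annotation))]
    ann <- ann[lengths(ann) > 0L]
    k <- length(ann)
    if (k < 2L) return(NA_real_)
    agree <- 0L
    for (i in seq_len(k))
      for (j in seq_len(k))
        if (i != j && length(intersect(ann[[i]], ann[[j]]))) agree <- agree + 1L
    agree / (k * (k - 1L))
  })
  scorable <- per_cluster[!is.na(per_cluster)]
  if (!length(scorable))
    stop("no cluster contains two or more annotated genes")
  mean(scorable)
}
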