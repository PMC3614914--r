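#' Read an expression time-course matrix from TSV
#'
#' Expected dialect: tab-separated text; a header row giving the numeric
#' time values (optionally preceded by a label for the id column); every
#' following row is a gene id followed by one numeric value per time point.
#' Rows are normalised to mean 0 / sd 1 on load (with a log note), matching
#' the model's assumption. Malformed input (ragged rows, non-numeric cells,
#' duplicate ids or times) raises an error naming the offending line.
#'
#' @param path input file.
#' @param normalise row-standardise on load (default `TRUE`).
#' @return a [ts_expr()].
#' @export
read_expression_tsv <- function(path, normalise = TRUE) {
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("expected a header row and at least one gene")
  fields <- strsplit(lines, "\t", fixed = TRUE)

  hdr <- fields[[1L]]
  times <- suppressWarnings(as.numeric(hdr))
  if (is.na(times[1L])) times <- times[-1L]  # leading id-column label
  if (anyNA(times))
    stop("line 1: header must contain numeric time values")
  q <- length(times)
  tryCatch(validate_time_grid(times),
           error = function(e) stop("line 1: ", conditionMessage(e)))

  body <- fields[-1L]
  n <- length(body)
  ids <- character(n)
  values <- matrix(NA_real_, n, q)
  for (i in seq_len(n)) {
    row <- body[[i]]
    if (length(row) != q + 1L)
      stop(sprintf("line %d: expected %d fields, found %d",
                   i + 1L, q + 1L, length(row)))
    ids[i] <- row[1L]
    v <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(v))
      stop(sprintf("line %d: non-numeric value in column %d for gene '%s'",
                   i + 1L, which(is.na(v))[1L] + 1L, row[1L]))
    values[i, ] <- v
  }
  if (anyDuplicated(ids))
    stop("duplicate gene id: ", ids[duplicated(ids)][1L])
  if (normalise)
    message(sprintf("read %d genes x %d time points; rows normalised to mean 0 / sd 1",
                    n, q))
  ts_expr(values, times, gene_ids = ids, normalise = normalise)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_tsv()]: header `gene_id` plus the time values,
#' then one row per gene, values printed with 15 significant digits so a
#' round trip preserves them to 1e-12.
#'
#' @param expr a [ts_expr()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", format(expr$times, digits = 15,
                                       trim = TRUE, scientific = FALSE)),
                   collapse = "\t"), con)
  for (i in seq_len(nrow(expr$values)))
    writeLines(paste(c(expr$gene_ids[i],
                       sprintf("%.15g", expr$values[i, ])),
                     collapse = "\t"), con)
  invisible(path)
}

#' Write a dendrogram as Newick plus a node table
#'
#' The Newick file uses gene ids as leaf names; every internal node carries
#' its merge posterior r as a label (6 decimals) and each edge has length
#' 1 - r(parent), clamped at 0 — a visualisation convenience mapping
#' confident merges to short branches. Because Newick cannot portably carry
#' all node statistics, a companion TSV (`<path>.nodes.tsv`) lists, for each
#' of the 2n - 1 nodes: node_id, child ids, n_k, log_pH1, log_pT, r.
#'
#' @param tree a `bhc_dendrogram`.
#' @param path output Newick file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(tree, path) {
  fmt_node <- function(id) {
    nd <- tree$nodes[[id]]
    if (is.na(nd$left)) return(tree$gene_ids[nd$members[1L]])
    sprintf("(%s,%s)%.6f", fmt_edge(nd$left, nd), fmt_edge(nd$right, nd),
            nd$r)
  }
  fmt_edge <- function(id, parent) {
    sprintf("%s:%.6f", fmt_node(id), max(0, 1 - parent$r))
  }
  writeLines(paste0(fmt_node(tree$root), ";"), path)

  tab <- do.call(rbind, lapply(seq_along(tree$nodes), function(id) {
    nd <- tree$nodes[[id]]
    data.frame(node_id = id, left = nd$left, right = nd$right,
               n_k = length(nd$members), log_pH1 = nd$logH1,
               log_pT = nd$logT, r = nd$r)
  }))
  utils::write.table(tab, paste0(path, ".nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a flat partition as TSV
#'
#' Two columns (`gene_id`, `cluster`); clusters are renumbered 1..K by
#' decreasing size (ties by first appearance).
#'
#' @param p named partition.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_partition <- function(p, path) {
  sizes <- table(p)
  ord <- names(sizes)[order(-as.vector(sizes),
                            match(names(sizes), unique(as.character(p))))]
  relab <- setNames(seq_along(ord), ord)
  out <- data.frame(gene_id = names(p),
                    cluster = as.integer(relab[as.character(p)]))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a partition written by [write_partition()]
#'
#' @param path input file.
#' @return named integer vector of cluster labels.
#' @export
read_partition <- function(path) {
  if (!file.exists(path)) stop("partition file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "cluster") %in% names(tab)))
    stop("partition file must have columns gene_id and cluster")
  setNames(as.integer(tab$cluster), tab$gene_id)
}

#' Read an annotation map from TSV
#'
#' Two columns (`gene_id`, `term`), one row per gene-term pair.
#'
#' @param path input file.
#' @return named list: gene id -> character vector of terms.
#' @export
read_annotation_tsv <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "term") %in% names(tab)))
    stop("annotation file must have columns gene_id and term")
  split(as.character(tab$term), tab$gene_id)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a clustering run exactly: input
#' path, mode, alpha, m, seed, cut threshold, software version and
#' timestamps.
#'
#' @param path output JSON file.
#' @param input input expression file.
#' @param mode `"greedy"` or `"randomised"`.
#' @param config a [bhc_config()].
#' @param rcfg a [randomised_config()] or `NULL` for greedy runs.
#' @param started,finished POSIXct timestamps.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, input, mode, config, rcfg = NULL,
                           started = Sys.time(), finished = Sys.time()) {
  manifest <- list(
    input = input, mode = mode, alpha = config$alpha,
    cut_threshold = config$cut_threshold,
    m = if (is.null(rcfg)) NULL else rcfg$m,
    seed = if (is.null(rcfg)) NULL else rcfg$seed,
    consolidate = if (is.null(rcfg)) NULL else rcfg$consolidate,
    version = as.character(utils::packageVersion("tsbhc")),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest[!vapply(manifest, is.null, TRUE)], path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a run manifest
#'
#' @param path manifest JSON file.
#' @return named list of run parameters.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
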