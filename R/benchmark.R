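#' Sweep the randomised algorithm over subset sizes
#'
#' For each combination of subset size m and seed, runs [randomised_bhc()]
#' on the supplied data, cuts the tree, and records the adjusted Rand index
#' against the ground truth, the number of clusters, the GP-likelihood
#' evaluation count (the hardware-free work measure) and the wall time. A
#' greedy baseline row (m recorded as `"greedy"`) is always included.
#' Individual run failures are recorded (`NA` metrics) and the sweep
#' continues.
#'
#' @param expr a [ts_expr()] object.
#' @param truth named ground-truth partition.
#' @param m_values integer vector of subset sizes.
#' @param seeds integer vector of seeds (each m is run once per seed).
#' @param config a [bhc_config()].
#' @param consolidate passed to [randomised_config()].
#' @return list with `runs` (data.frame: m, seed, ari, n_clusters, gp_evals,
#'   seconds) and `summary` (per-m mean ARI and standard error on the mean,
#'   greedy baseline included).
#' @export
benchmark_sweep <- function(expr, truth, m_values, seeds,
                            config = bhc_config(), consolidate = TRUE) {
  one_run <- function(fun) {
    reset_gp_eval_count()
    t0 <- proc.time()[["elapsed"]]
    part <- tryCatch(cut_dendrogram(fun()), error = function(e) {
      warning("benchmark run failed: ", conditionMessage(e))
      NULL
    })
    secs <- proc.time()[["elapsed"]] - t0
    if (is.null(part))
      return(list(ari = NA_real_, k = NA_integer_,
                  evals = gp_eval_count(), secs = secs))
    list(ari = adjusted_rand_index(part, truth),
         k = length(unique(part)), evals = gp_eval_count(), secs = secs)
  }

  base <- one_run(function() greedy_bhc(expr, config))
  rows <- list(data.frame(m = "greedy", seed = NA_integer_, ari = base$ari,
                          n_clusters = base$k, gp_evals = base$evals,
                          seconds = base$secs, stringsAsFactors = FALSE))
  for (m in m_values) {
    for (s in seeds) {
      res <- one_run(function() randomised_bhc(
        expr, config, randomised_config(m = m, seed = s,
                                        consolidate = consolidate)))
      rows[[length(rows) + 1L]] <-
        data.frame(m = as.character(m), seed = as.integer(s), ari = res$ari,
                   n_clusters = res$k, gp_evals = res$evals,
                   seconds = res$secs, stringsAsFactors = FALSE)
    }
  }
  runs <- do.call(rbind, rows)
  grp <- split(runs$ari, runs$m)
  summary <- data.frame(
    m = names(grp),
    mean_ari = vapply(grp, function(v) mean(v, na.rm = TRUE), 1),
    se_ari = vapply(grp, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2L) NA_real_ else sd(v) / sqrt(length(v))
    }, 1),
    row.names = NULL, stringsAsFactors = FALSE)
  list(runs = runs, summary = summary)
}

#' Write a benchmark run table as TSV
#'
#' @param sweep result of [benchmark_sweep()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_benchmark_tsv <- function(sweep, path) {
  utils::write.table(sweep$runs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
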