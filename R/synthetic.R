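#' Configuration for the synthetic time-course generator
#'
#' Describes a mixture of GP-generated clusters: each cluster has one latent
#' trajectory drawn from a zero-mean GP with noise-free squared-exponential
#' covariance on the shared grid, and member genes observe it through iid
#' Gaussian noise.
#'
#' @param n_clusters number of clusters K.
#' @param genes_per_cluster integer vector of cluster sizes (recycled to
#'   length K).
#' @param times shared time grid.
#' @param hyper a single [gp_hyper()] used for every cluster, or a list of K
#'   of them.
#' @param seed integer seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_clusters, genes_per_cluster, times,
                             hyper = gp_hyper(1, 2, 0.05), seed = 1L) {
  n_clusters <- as.integer(n_clusters)
  if (n_clusters < 1L) stop("n_clusters must be >= 1")
  sizes <- as.integer(rep_len(genes_per_cluster, n_clusters))
  if (any(sizes < 1L)) stop("cluster sizes must be >= 1")
  validate_time_grid(times)
  if (inherits(hyper, "gp_hyper") || (is.numeric(hyper) && length(hyper) == 3L))
    hyper <- rep(list(hyper), n_clusters)
  if (length(hyper) != n_clusters)
    stop("hyper must be one gp_hyper or a list of n_clusters of them")
  # unlike the model side, the generator permits exactly-zero observation noise
  hyper <- lapply(hyper, function(h) {
    h <- setNames(as.numeric(h),
                  c("signal_variance", "length_scale", "noise_variance"))
    if (h[["signal_variance"]] <= 0 || h[["length_scale"]] <= 0 ||
        h[["noise_variance"]] < 0)
      stop("generator hyperparameters must be positive (noise may be zero)")
    h
  })
  structure(list(n_clusters = n_clusters, genes_per_cluster = sizes,
                 times = as.numeric(times), hyper = hyper,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Named simulation profiles
#'
#' `"benchmark"` mirrors the shape of the large synthetic evaluation set:
#' 1000 genes in 13 clusters of unequal size, 17 time points. `"fast"` is
#' the small evaluation profile (4 well-separated clusters of 15 genes, 10
#' time points, noise variance 0.05); `"tiny"` is a minimal smoke-test
#' profile.
#'
#' @param name one of `"benchmark"`, `"fast"`, `"tiny"`.
#' @param seed integer seed stored in the config.
#' @return a [synthetic_config()].
#' @export
synthetic_profile <- function(name = c("fast", "benchmark", "tiny"),
                              seed = 1L) {
  switch(match.arg(name),
    fast = synthetic_config(4L, 15L, times = 0:9,
                            hyper = gp_hyper(1, 2, 0.05), seed = seed),
    benchmark = synthetic_config(
      13L,
      c(200L, 150L, 120L, 100L, 90L, 80L, 70L, 60L, 50L, 30L, 20L, 15L, 15L),
      times = 0:16, hyper = gp_hyper(1, 2.5, 0.1), seed = seed),
    tiny = synthetic_config(3L, 4L, times = 0:7,
                            hyper = gp_hyper(1, 2, 0.05), seed = seed))
}

#' Draw latent functions from the GP prior
#'
#' @param times time grid of length q.
#' @param hyper a [gp_hyper()]; only the noise-free kernel is used.
#' @param n_draws number of independent realisations.
#' @return n_draws x q matrix of GP realisations.
#' @export
gp_prior_draw <- function(times, hyper, n_draws = 1L) {
  h <- setNames(as.numeric(hyper)[1:3],
                c("signal_variance", "length_scale", "noise_variance"))
  # the noise entry is unused here; substitute 1 so zero-noise generator
  # configs validate
  K <- se_covariance(times, gp_hyper(h[[1L]], h[[2L]], 1),
                     include_noise = FALSE)
  diag(K) <- diag(K) + 1e-8
  L <- t(chol(K))
  Z <- matrix(rnorm(n_draws * length(times)), length(times), n_draws)
  t(L %*% Z)
}

#' Generate synthetic expression data with known ground truth
#'
#' Draws one latent trajectory per cluster from the GP prior and adds iid
#' Gaussian observation noise per gene, then (by default) row-normalises —
#' the same generative model the clustering engine assumes, so recovery of
#' the ground-truth labels is a well-posed test. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg a [synthetic_config()].
#' @param normalise row-standardise the returned matrix (default `TRUE`).
#' @return list with `expr` (a [ts_expr()]), `labels` (named integer
#'   ground-truth partition), and `latents` (K x q matrix of cluster
#'   trajectories).
#' @export
generate_synthetic <- function(cfg, normalise = TRUE) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_local_seed(cfg$seed, {
    q <- length(cfg$times)
    n <- sum(cfg$genes_per_cluster)
    values <- matrix(0, n, q)
    labels <- integer(n)
    latents <- matrix(0, cfg$n_clusters, q)
    row <- 0L
    for (k in seq_len(cfg$n_clusters)) {
      h <- cfg$hyper[[k]]
      f <- gp_prior_draw(cfg$times, h, 1L)[1L, ]
      latents[k, ] <- f
      sd_n <- sqrt(h[["noise_variance"]])
      for (g in seq_len(cfg$genes_per_cluster[k])) {
        row <- row + 1L
        values[row, ] <- f + rnorm(q, sd = sd_n)
        labels[row] <- k
      }
    }
    ids <- paste0("gene", seq_len(n))
    expr <- ts_expr(values, cfg$times, gene_ids = ids, normalise = normalise)
    list(expr = expr, labels = setNames(labels, ids), latents = latents)
  })
}
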