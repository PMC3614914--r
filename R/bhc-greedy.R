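#' BHC configuration
#'
#' @param alpha positive Dirichlet-process concentration. Fixed (not learned);
#'   the small default encodes a prior assumption of only weak clustering.
#' @param cut_threshold merge-posterior threshold for cutting the dendrogram
#'   into flat clusters; inclusive (a node with r equal to the threshold is
#'   kept merged). Default 0.5: a merge is accepted when it is more likely
#'   than not.
#' @return list of class `bhc_config`.
#' @export
bhc_config <- function(alpha = 0.001, cut_threshold = 0.5) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("alpha must be a positive scalar")
  if (cut_threshold <= 0 || cut_threshold >= 1)
    stop("cut_threshold must lie in (0, 1)")
  structure(list(alpha = alpha, cut_threshold = cut_threshold),
            class = "bhc_config")
}

#' Dirichlet-process-mixture merge prior
#'
#' For a proposed merge of clusters with n_i and n_j members, the DPM weights
#' follow the recursion d_k = alpha * Gamma(n_k) + d_i * d_j and
#' pi_k = alpha * Gamma(n_k) / d_k with n_k = n_i + n_j; leaves carry
#' d = alpha, pi = 1. All arithmetic is in log space (log-sum-exp), since d_k
#' grows factorially.
#'
#' @param left,right `bhc_node` objects with disjoint member sets.
#' @param alpha positive DPM concentration.
#' @return list with `log_d`, `log_pi`, and `log_1mpi` for the merged
#'   cluster. `log_1mpi` = log(1 - pi_k) is computed directly as
#'   log(d_i d_j) - log(d_k): recovering it from `log_pi` would underflow
#'   catastrophically high in the tree, where pi_k is within machine epsilon
#'   of 1 yet the split route still matters.
#' @export
dpm_merge_prior <- function(left, right, alpha) {
  if (length(intersect(left$members, right$members)))
    stop("cluster member sets must be disjoint")
  n_k <- length(left$members) + length(right$members)
  log_a <- log(alpha) + lgamma(n_k)
  log_dd <- left$log_d + right$log_d
  log_d <- log_sum_exp(log_a, log_dd)
  list(log_d = log_d, log_pi = log_a - log_d, log_1mpi = log_dd - log_d)
}

new_leaf_node <- function(member, alpha, fit) {
  structure(list(members = as.integer(member), left = NA_integer_,
                 right = NA_integer_, log_d = log(alpha), log_pi = 0,
                 logH1 = fit$logLik, logT = fit$logLik, r = NA_real_,
                 hyper = fit$hyper, warn = isTRUE(fit$warn)),
            class = "bhc_node")
}

# starting hyperparameters for a merge candidate: the optimum of the child
# with the higher per-gene average marginal likelihood
merge_init_hyper <- function(left, right) {
  if (left$logH1 / length(left$members) >=
      right$logH1 / length(right$members)) left$hyper else right$hyper
}

#' Posterior probability that two clusters share one latent function
#'
#' Builds the merged `bhc_node`: hyperparameters are re-optimised on the
#' pooled data for the single-cluster hypothesis H1; the tree likelihood
#' mixes H1 with the product of the children's tree likelihoods using the DPM
#' prior; the merge posterior is r = pi * p(D|H1) / p(D|T), in (0, 1].
#'
#' @param left,right `bhc_node` objects with disjoint member sets.
#' @param alpha positive DPM concentration.
#' @param loglik likelihood provider: `function(members, init)` returning a
#'   list with `logLik`, `hyper`, `warn` — see [make_gp_loglik()].
#' @return merged `bhc_node` (children are referenced by the caller, not
#'   stored here as ids).
#' @export
merge_posterior <- function(left, right, alpha, loglik) {
  prior <- dpm_merge_prior(left, right, alpha)
  members <- sort(c(left$members, right$members))
  fit <- loglik(members, merge_init_hyper(left, right))
  logH1 <- fit$logLik
  log_joint_merge <- prior$log_pi + logH1
  log_joint_split <- prior$log_1mpi + left$logT + right$logT
  logT <- log_sum_exp(log_joint_merge, log_joint_split)
  r <- exp(log_joint_merge - logT)
  structure(list(members = members, left = NA_integer_, right = NA_integer_,
                 log_d = prior$log_d, log_pi = prior$log_pi,
                 logH1 = logH1, logT = logT, r = r, hyper = fit$hyper,
                 warn = isTRUE(fit$warn)),
            class = "bhc_node")
}

#' GP likelihood provider for the clustering engine
#'
#' Returns a closure that, given a set of gene indices and starting
#' hyperparameters, pools the corresponding rows and maximises the
#' shared-function GP marginal likelihood.
#'
#' @param expr a [ts_expr()] object.
#' @param ... passed to [optimise_hyperparams()].
#' @return `function(members, init)` -> list(logLik, hyper, warn).
#' @export
make_gp_loglik <- function(expr, ...) {
  force(expr)
  function(members, init = NULL) {
    optimise_hyperparams(expr$values[members, , drop = FALSE], expr$times,
                         init = init, ...)
  }
}

#' Initialise one leaf per gene
#'
#' Each gene starts in its own cluster with d = alpha, pi = 1, and its H1
#' marginal likelihood maximised over the GP hyperparameters (for a leaf the
#' tree likelihood equals the H1 likelihood).
#'
#' @param expr a [ts_expr()] object with at least 2 genes.
#' @param config a [bhc_config()].
#' @param loglik likelihood provider; defaults to [make_gp_loglik()] on
#'   `expr`.
#' @return list of `bhc_node` leaves, one per gene.
#' @export
init_leaves <- function(expr, config = bhc_config(), loglik = NULL) {
  n <- nrow(expr$values)
  if (n < 2L) stop("need at least 2 genes to cluster")
  if (is.null(loglik)) loglik <- make_gp_loglik(expr)
  lapply(seq_len(n), function(i)
    new_leaf_node(i, config$alpha, loglik(i, NULL)))
}

# --- core agglomeration over an arbitrary active set of existing nodes -----
#
# `nodes` is a pool (list indexed by id); agglomeration runs over the ids in
# `active`, appending internal nodes to the pool. Candidates are cached
# across iterations; after a merge only the pairs that involve the new node
# are evaluated. Selection: highest r, ties broken by the lexicographically
# smallest (min left member, min right member) pair.
bhc_build <- function(nodes, active, alpha, loglik) {
  active <- as.integer(active)

  cand_i <- integer(0); cand_j <- integer(0)
  cand_r <- numeric(0); cand_node <- list()
  add_candidate <- function(i, j) {
    node <- tryCatch(merge_posterior(nodes[[i]], nodes[[j]], alpha, loglik),
                     error = function(e) NULL)
    r <- if (is.null(node) || !is.finite(node$logT)) NA_real_ else node$r
    cand_i[[length(cand_i) + 1L]] <<- i
    cand_j[[length(cand_j) + 1L]] <<- j
    cand_r[[length(cand_r) + 1L]] <<- r
    cand_node[[length(cand_node) + 1L]] <<- node
  }

  n0 <- length(active)
  for (a in seq_len(n0 - 1L))
    for (b in seq(a + 1L, n0)) add_candidate(active[a], active[b])

  merges <- integer(0)
  while (length(active) > 1L) {
    ok <- which(!is.na(cand_r))
    if (!length(ok)) stop("all merge candidates failed numerically")
    best_r <- max(cand_r[ok])
    ties <- ok[cand_r[ok] == best_r]
    if (length(ties) > 1L) {
      key1 <- vapply(ties, function(k) min(nodes[[cand_i[k]]]$members), 1L)
      key2 <- vapply(ties, function(k) min(nodes[[cand_j[k]]]$members), 1L)
      lo <- pmin(key1, key2); hi <- pmax(key1, key2)
      ties <- ties[order(lo, hi)]
    }
    pick <- ties[1L]
    i <- cand_i[pick]; j <- cand_j[pick]
    node <- cand_node[[pick]]
    id <- length(nodes) + 1L
    node$left <- i; node$right <- j
    nodes[[id]] <- node
    merges <- c(merges, id)
    active <- setdiff(active, c(i, j))

    keep <- cand_i != i & cand_i != j & cand_j != i & cand_j != j
    cand_i <- cand_i[keep]; cand_j <- cand_j[keep]
    cand_r <- cand_r[keep]; cand_node <- cand_node[keep]
    for (a in active) add_candidate(a, id)
    active <- c(active, id)
  }
  list(nodes = nodes, root = active, merges = merges)
}

#' Greedy Bayesian hierarchical clustering
#'
#' Starts from one cluster per gene and repeatedly merges the pair with the
#' highest posterior merge probability until a single cluster remains,
#' producing a complete binary dendrogram annotated with DPM weights,
#' marginal likelihoods, optimised hyperparameters and merge posteriors at
#' every internal node. Deterministic for a fixed input.
#'
#' @param expr a [ts_expr()] object (n >= 2 genes).
#' @param config a [bhc_config()].
#' @param loglik optional likelihood provider override (used for testing);
#'   defaults to the GP provider on `expr`.
#' @return object of class `bhc_dendrogram`: list with `nodes` (length
#'   2n - 1), `root`, `merges` (internal-node ids in merge order),
#'   `gene_ids`, `times`, `config`.
#' @examples
#' \donttest{
#' sim <- generate_synthetic(synthetic_profile("tiny"))
#' tree <- greedy_bhc(sim$expr)
#' cut_dendrogram(tree)
#' }
#' @export
greedy_bhc <- function(expr, config = bhc_config(), loglik = NULL) {
  if (is.null(loglik)) loglik <- make_gp_loglik(expr)
  leaves <- init_leaves(expr, config, loglik)
  built <- bhc_build(leaves, seq_along(leaves), config$alpha, loglik)
  new_dendrogram(built, expr, config)
}

new_dendrogram <- function(built, expr, config) {
  structure(list(nodes = built$nodes, root = built$root,
                 merges = built$merges, gene_ids = expr$gene_ids,
                 times = expr$times, config = config),
            class = "bhc_dendrogram")
}

#' @export
print.bhc_dendrogram <- function(x, ...) {
  n <- sum(vapply(x$nodes, function(nd) is.na(nd$left), TRUE))
  root_r <- x$nodes[[x$root]]$r
  cat(sprintf("bhc_dendrogram: %d genes, %d internal nodes, root r = %.4g\n",
              n, length(x$nodes) - n, root_r))
  k <- length(unique(cut_dendrogram(x, x$config$cut_threshold)))
  cat(sprintf("cut at %.2f: %d clusters\n", x$config$cut_threshold, k))
  invisible(x)
}

#' Cut a dendrogram into a flat partition
#'
#' Clusters are the maximal subtrees whose root has merge posterior
#' r >= threshold (leaves count as r = 1): starting at the root, the tree is
#' descended while r falls below the threshold, and each first node at or
#' above it becomes one cluster.
#'
#' @param tree a `bhc_dendrogram`.
#' @param threshold cut threshold in (0, 1); defaults to the tree's config.
#' @return named integer vector: cluster label (contiguous, from 1) per gene
#'   id, in input gene order.
#' @export
cut_dendrogram <- function(tree, threshold = NULL) {
  if (is.null(threshold)) threshold <- tree$config$cut_threshold
  labels <- integer(length(tree$gene_ids))
  k <- 0L
  stack <- tree$root
  while (length(stack)) {
    id <- stack[[1L]]; stack <- stack[-1L]
    nd <- tree$nodes[[id]]
    if (is.na(nd$left) || (!is.na(nd$r) && nd$r >= threshold)) {
      k <- k + 1L
      labels[nd$members] <- k
    } else {
      stack <- c(nd$left, nd$right, stack)
    }
  }
  setNames(labels, tree$gene_ids)
}
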