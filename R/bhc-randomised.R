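#' Configuration for the randomised BHC algorithm
#'
#' @param m subset size used at each recursion level (>= 2). `NULL` (the
#'   default) resolves at run time to n/10 clamped to `[20, n]`, a moderate
#'   value trading speed against fidelity to the greedy result.
#' @param seed integer seed; all randomness in the run flows from it.
#' @param consolidate recompute every internal node's statistics (DPM
#'   weights, marginal likelihoods, merge posterior) from full memberships in
#'   a final bottom-up pass, so the 0.5 cut is well-defined at splice nodes.
#'   Default `TRUE`; `FALSE` keeps the subset-estimated statistics at splice
#'   nodes (faster, approximate).
#' @return list of class `randomised_config`.
#' @export
randomised_config <- function(m = NULL, seed = 1L, consolidate = TRUE) {
  if (!is.null(m)) {
    m <- as.integer(m)
    if (is.na(m) || m < 2L) stop("m must be an integer >= 2")
  }
  structure(list(m = m, seed = as.integer(seed),
                 consolidate = isTRUE(consolidate)),
            class = "randomised_config")
}

#' Uniform random gene subset
#'
#' Samples `min(m, n)` indices without replacement, deterministically for a
#' given seed; the global RNG state is left untouched.
#'
#' @param gene_indices integer vector to sample from.
#' @param m target subset size.
#' @param seed integer seed.
#' @return sorted integer subset.
#' @export
sample_subset <- function(gene_indices, m, seed) {
  n <- length(gene_indices)
  if (m >= n) return(sort(gene_indices))
  with_local_seed(seed, sort(gene_indices[sample.int(n, m)]))
}

#' Route one gene through a top-level split
#'
#' Assigns the gene to the branch under whose fitted single-cluster GP model
#' it has the higher predictive density:
#' `log p(g | D_B) = log p(g, D_B | H1, theta_B) - log p(D_B | H1, theta_B)`
#' evaluated at the branch's optimised hyperparameters. Branch-constant
#' prior and tree-likelihood factors cancel in this comparison, which is what
#' makes routing reliable even when one branch is a mixture of several
#' clusters (a mixture's inflated fitted noise gives middling predictive
#' scores that lose to the gene's own cluster but beat a wrong pure branch).
#' Exact ties go left. A GP failure on one side assigns to the other side
#' with a warning; failure on both is an error naming the gene.
#'
#' @param leaf the gene's `bhc_node` leaf.
#' @param left,right the two branch `bhc_node`s.
#' @param expr the [ts_expr()] the nodes index into.
#' @param base_left,base_right optional precomputed branch baselines
#'   `log p(D_B | H1, theta_B)` (saves two evaluations per gene when
#'   filtering many genes through one split).
#' @return list with `branch` ("left"/"right") and the two predictive
#'   scores `score_left`, `score_right`.
#' @export
filter_gene <- function(leaf, left, right, expr,
                        base_left = NULL, base_right = NULL) {
  g <- leaf$members[1L]
  side <- function(branch, base) {
    tryCatch({
      if (is.null(base))
        base <- log_marginal_fast(expr$values[branch$members, , drop = FALSE],
                                  expr$times, branch$hyper)
      pooled <- log_marginal_fast(
        expr$values[c(g, branch$members), , drop = FALSE],
        expr$times, branch$hyper)
      pooled - base
    }, error = function(e) NA_real_)
  }
  sl <- side(left, base_left)
  sr <- side(right, base_right)
  if (is.na(sl) && is.na(sr))
    stop("filtering failed on both branches for gene ", g)
  if (is.na(sl)) {
    warning("filtering failed on left branch for gene ", g)
    return(list(branch = "right", score_left = sl, score_right = sr))
  }
  if (is.na(sr)) {
    warning("filtering failed on right branch for gene ", g)
    return(list(branch = "left", score_left = sl, score_right = sr))
  }
  list(branch = if (sl >= sr) "left" else "right",
       score_left = sl, score_right = sr)
}

#' Randomised Bayesian hierarchical clustering
#'
#' Divide-and-filter acceleration of [greedy_bhc()]: cluster a random subset
#' of m genes greedily, keep only the top split of that tree, route every
#' remaining gene to the branch with the higher predictive density under the
#' branch's fitted model (see [filter_gene()]), then recurse independently
#' on each branch's full gene set with
#' a fresh subsample; subsets of size <= m are completed with the greedy
#' algorithm. With `m >= n` this reduces exactly to [greedy_bhc()]. The
#' result is a complete binary dendrogram over all genes; by default it is
#' consolidated (see [consolidate_tree()]) so every merge posterior reflects
#' full memberships before cutting.
#'
#' @param expr a [ts_expr()] object (n >= 2 genes).
#' @param config a [bhc_config()].
#' @param rcfg a [randomised_config()].
#' @param loglik optional likelihood provider override.
#' @return a `bhc_dendrogram` (see [greedy_bhc()]).
#' @export
randomised_bhc <- function(expr, config = bhc_config(),
                           rcfg = randomised_config(), loglik = NULL) {
  n <- nrow(expr$values)
  if (n < 2L) stop("need at least 2 genes to cluster")
  m <- rcfg$m
  if (is.null(m)) m <- min(max(20L, as.integer(round(n / 10))), n)
  if (is.null(loglik)) loglik <- make_gp_loglik(expr)

  if (m >= n) {
    message("randomised BHC with m >= n reduces to the greedy algorithm")
    return(greedy_bhc(expr, config, loglik))
  }

  env <- new.env(parent = emptyenv())
  env$nodes <- init_leaves(expr, config, loglik)
  env$merges <- integer(0)

  rbhc <- function(idx, seed) {
    n_i <- length(idx)
    if (n_i == 1L) return(idx)
    if (n_i <= m) {
      built <- bhc_build(env$nodes, idx, config$alpha, loglik)
      env$nodes <- built$nodes
      env$merges <- c(env$merges, built$merges)
      return(built$root)
    }
    seeds <- with_local_seed(seed, {
      subset <- sort(idx[sample.int(n_i, m)])
      list(subset = subset, left = sample.int(2147483646L, 1L),
           right = sample.int(2147483646L, 1L))
    })
    subset <- seeds$subset
    sub <- bhc_build(env$nodes, subset, config$alpha, loglik)
    sub_root <- sub$nodes[[sub$root]]
    lnode <- sub$nodes[[sub_root$left]]
    rnode <- sub$nodes[[sub_root$right]]

    rest <- setdiff(idx, subset)
    base_l <- log_marginal_fast(expr$values[lnode$members, , drop = FALSE],
                                expr$times, lnode$hyper)
    base_r <- log_marginal_fast(expr$values[rnode$members, , drop = FALSE],
                                expr$times, rnode$hyper)
    go_left <- vapply(rest, function(g) {
      filter_gene(env$nodes[[g]], lnode, rnode, expr,
                  base_left = base_l, base_right = base_r)$branch == "left"
    }, TRUE)
    left_set <- sort(c(lnode$members, rest[go_left]))
    right_set <- sort(c(rnode$members, rest[!go_left]))
    if (length(rest) && (all(go_left) || all(!go_left)))
      warning(sprintf(
        "unbalanced filtering: all %d genes routed one way (branch sizes %d/%d)",
        length(rest), length(left_set), length(right_set)))

    lid <- rbhc(left_set, seeds$left)
    rid <- rbhc(right_set, seeds$right)

    # splice node: DPM weights exact from children; likelihoods and r copied
    # from the subset-run root (approximate until consolidation)
    prior <- dpm_merge_prior(env$nodes[[lid]], env$nodes[[rid]], config$alpha)
    id <- length(env$nodes) + 1L
    env$nodes[[id]] <- structure(
      list(members = sort(c(left_set, right_set)), left = lid, right = rid,
           log_d = prior$log_d, log_pi = prior$log_pi,
           logH1 = sub_root$logH1, logT = sub_root$logT, r = sub_root$r,
           hyper = sub_root$hyper, warn = isTRUE(sub_root$warn),
           approx = TRUE),
      class = "bhc_node")
    env$merges <- c(env$merges, id)
    id
  }

  root <- rbhc(seq_len(n), rcfg$seed)
  tree <- new_dendrogram(list(nodes = env$nodes, root = root,
                              merges = env$merges), expr, config)
  if (rcfg$consolidate) tree <- consolidate_tree(tree, loglik = loglik)
  tree
}

#' Recompute dendrogram statistics from full memberships
#'
#' Single bottom-up pass over the tree recomputing, at every internal node,
#' the DPM weights, the H1 marginal likelihood (with hyperparameter
#' re-optimisation initialised from the children's optima), the tree
#' likelihood, and the merge posterior, using the node's full member set.
#' Idempotent; on a tree produced by [greedy_bhc()] it is a no-op up to
#' floating tolerance. A GP failure at a node keeps its prior estimate and
#' flags it.
#'
#' @param tree a `bhc_dendrogram`.
#' @param loglik optional likelihood provider; reconstructed from the tree's
#'   stored data via `expr` when supplied.
#' @param expr the [ts_expr()] the tree was built from (required when
#'   `loglik` is `NULL`).
#' @return the consolidated `bhc_dendrogram`.
#' @export
consolidate_tree <- function(tree, loglik = NULL, expr = NULL) {
  if (is.null(loglik)) {
    if (is.null(expr)) stop("supply either `loglik` or `expr`")
    loglik <- make_gp_loglik(expr)
  }
  nodes <- tree$nodes
  for (id in seq_along(nodes)) {
    nd <- nodes[[id]]
    if (is.na(nd$left)) next  # leaves are already exact
    l <- nodes[[nd$left]]; r <- nodes[[nd$right]]
    prior <- dpm_merge_prior(l, r, tree$config$alpha)
    fit <- tryCatch(loglik(nd$members, merge_init_hyper(l, r)),
                    error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$logLik)) {
      nd$warn <- TRUE
      nodes[[id]] <- nd
      next
    }
    nd$log_d <- prior$log_d
    nd$log_pi <- prior$log_pi
    nd$logH1 <- fit$logLik
    lm <- prior$log_pi + fit$logLik
    ls <- prior$log_1mpi + l$logT + r$logT
    nd$logT <- log_sum_exp(lm, ls)
    nd$r <- exp(lm - nd$logT)
    nd$hyper <- fit$hyper
    nd$warn <- isTRUE(fit$warn)
    nd$approx <- NULL
    nodes[[id]] <- nd
  }
  tree$nodes <- nodes
  tree
}
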