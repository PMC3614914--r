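# Randomised BHC: subset sampling, filtering, recursion, consolidation.

test_that("sample_subset is uniform, deterministic, and clamps m", {
  expect_identical(sample_subset(5:10, 99, seed = 1), 5:10)
  expect_identical(sample_subset(1:100, 10, seed = 7),
                   sample_subset(1:100, 10, seed = 7))
  expect_false(identical(sample_subset(1:100, 10, seed = 7),
                         sample_subset(1:100, 10, seed = 8)))
  # inclusion frequency ~ m/n over many seeds
  counts <- integer(1000)
  for (s in 1:200) {
    sub <- sample_subset(1:1000, 100, seed = s)
    counts[sub] <- counts[sub] + 1L
  }
  freq <- counts / 200
  expect_equal(mean(freq), 0.1, tolerance = 1e-9)   # exactly m/n on average
  expect_lt(max(abs(freq - 0.1)), 0.12)             # no gross non-uniformity
  # global RNG state is untouched
  set.seed(123); before <- .Random.seed
  invisible(sample_subset(1:50, 10, seed = 99))
  expect_identical(.Random.seed, before)
})

make_split_fixture <- function(seed = 5) {
  sim <- generate_synthetic(synthetic_config(2, 6, times = 0:7,
                                             hyper = gp_hyper(1, 2, 0.03),
                                             seed = seed))
  expr <- sim$expr
  cfg <- bhc_config()
  loglik <- make_gp_loglik(expr)
  leaves <- init_leaves(expr, cfg, loglik)
  # branches = the two true clusters, fitted as single clusters
  mk_branch <- function(idx) {
    fit <- loglik(idx, NULL)
    structure(list(members = idx, left = NA_integer_, right = NA_integer_,
                   log_d = 0, log_pi = 0, logH1 = fit$logLik,
                   logT = fit$logLik, r = NA_real_, hyper = fit$hyper,
                   warn = FALSE), class = "bhc_node")
  }
  list(sim = sim, expr = expr, leaves = leaves,
       left = mk_branch(1:5), right = mk_branch(7:11))
}

test_that("filter_gene routes genes to their own cluster's branch", {
  fx <- make_split_fixture()
  # gene 6 belongs to cluster 1 (left branch), gene 12 to cluster 2 (right)
  d6 <- filter_gene(fx$leaves[[6]], fx$left, fx$right, fx$expr)
  d12 <- filter_gene(fx$leaves[[12]], fx$left, fx$right, fx$expr)
  expect_identical(d6$branch, "left")
  expect_identical(d12$branch, "right")
  expect_gt(d6$score_left, d6$score_right)
  # swapping the branches flips the label but not the decision
  d6s <- filter_gene(fx$leaves[[6]], fx$right, fx$left, fx$expr)
  expect_identical(d6s$branch, "right")
  expect_equal(d6s$score_right, d6$score_left, tolerance = 1e-12)
  # precomputed baselines change nothing
  bl <- log_marginal_fast(fx$expr$values[fx$left$members, ], fx$expr$times,
                          fx$left$hyper)
  d6b <- filter_gene(fx$leaves[[6]], fx$left, fx$right, fx$expr,
                     base_left = bl)
  expect_identical(d6b$branch, "left")
  expect_equal(d6b$score_left, d6$score_left, tolerance = 1e-12)
})

test_that("filter_gene ties go left and failures fall to the other side", {
  fx <- make_split_fixture()
  # identical branches => exactly equal scores => left by tie-break
  d <- filter_gene(fx$leaves[[6]], fx$left, fx$left, fx$expr)
  expect_identical(d$branch, "left")
  # corrupt one branch's hyperparameters to force a one-sided failure
  broken <- fx$right
  broken$hyper <- c(signal_variance = NaN, length_scale = 1,
                    noise_variance = 0.1)
  expect_warning(
    d2 <- filter_gene(fx$leaves[[6]], broken, fx$left, fx$expr),
    "failed on left")
  expect_identical(d2$branch, "right")
  expect_error(
    suppressWarnings(filter_gene(fx$leaves[[6]], broken, broken, fx$expr)),
    "gene 6")
})

test_that("m >= n reduces the randomised algorithm to greedy exactly", {
  sim <- generate_synthetic(synthetic_profile("tiny", seed = 2))
  pg <- cut_dendrogram(greedy_bhc(sim$expr))
  for (s in c(1, 99)) {
    tr <- suppressMessages(randomised_bhc(
      sim$expr, rcfg = randomised_config(m = 50, seed = s)))
    expect_equal(adjusted_rand_index(cut_dendrogram(tr), pg), 1.0)
  }
})

test_that("randomised tree covers every gene once and is reproducible", {
  sim <- generate_synthetic(synthetic_profile("fast", seed = 4))
  rc <- randomised_config(m = 12, seed = 11)
  t1 <- suppressWarnings(randomised_bhc(sim$expr, rcfg = rc))
  t2 <- suppressWarnings(randomised_bhc(sim$expr, rcfg = rc))
  expect_identical(t1$nodes, t2$nodes)
  n <- nrow(sim$expr$values)
  expect_length(t1$nodes, 2L * n - 1L)
  leaves <- Filter(function(nd) is.na(nd$left), t1$nodes)
  expect_identical(sort(unlist(lapply(leaves, `[[`, "members"))), seq_len(n))
  for (id in t1$merges) {
    nd <- t1$nodes[[id]]
    kids <- sort(c(t1$nodes[[nd$left]]$members, t1$nodes[[nd$right]]$members))
    expect_identical(nd$members, kids)
  }
  # a different seed gives a different tree (overwhelmingly)
  t3 <- suppressWarnings(randomised_bhc(sim$expr,
                                        rcfg = randomised_config(m = 12,
                                                                 seed = 12)))
  expect_false(identical(t1$nodes, t3$nodes))
})

test_that("consolidation is a no-op on greedy trees and idempotent", {
  sim <- generate_synthetic(synthetic_profile("tiny", seed = 5))
  tree <- greedy_bhc(sim$expr)
  c1 <- consolidate_tree(tree, expr = sim$expr)
  for (id in tree$merges) {
    expect_equal(c1$nodes[[id]]$logT, tree$nodes[[id]]$logT,
                 tolerance = 1e-8)
    expect_equal(c1$nodes[[id]]$r, tree$nodes[[id]]$r, tolerance = 1e-8)
  }
  c2 <- consolidate_tree(c1, expr = sim$expr)
  for (id in tree$merges)
    expect_equal(c2$nodes[[id]]$logT, c1$nodes[[id]]$logT, tolerance = 1e-10)
})

test_that("consolidated splice nodes match the enumeration oracle", {
  # randomised run on a tiny problem, then check the root's tree likelihood
  # against brute force with the *same* fitted H1 values
  sim <- generate_synthetic(synthetic_config(2, 2, times = 0:5,
                                             hyper = gp_hyper(1, 2, 0.05),
                                             seed = 8))
  cfg <- bhc_config()
  tree <- suppressWarnings(randomised_bhc(
    sim$expr, cfg, randomised_config(m = 2, seed = 3)))
  # reconstruct the tree shape and H1 table from the fitted nodes
  shape_of <- function(id) {
    nd <- tree$nodes[[id]]
    if (is.na(nd$left)) return(nd$members[1])
    list(shape_of(nd$left), shape_of(nd$right))
  }
  shape <- shape_of(tree$root)
  tbl <- list()
  for (nd in tree$nodes) tbl[[memb_key(nd$members)]] <- nd$logH1
  # subsets that are not tree nodes never enter the recursion; enum needs
  # only tree-node keys, which the loop above provides
  expect_equal(tree$nodes[[tree$root]]$logT,
               log(enum_pT(shape, cfg$alpha, tbl)), tolerance = 1e-8)
})

test_that("randomised recursion always shrinks the problem", {
  sim <- generate_synthetic(synthetic_profile("fast", seed = 6))
  # m = 2 forces maximal recursion depth; must terminate and stay complete
  tr <- suppressWarnings(randomised_bhc(sim$expr,
                                        rcfg = randomised_config(m = 2,
                                                                 seed = 2)))
  n <- nrow(sim$expr$values)
  expect_length(tr$nodes, 2L * n - 1L)
  expect_identical(sort(tr$nodes[[tr$root]]$members), seq_len(n))
})
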