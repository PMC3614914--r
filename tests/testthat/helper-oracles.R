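# Independent oracles used across the test files. These are deliberately
# written by brute force / enumeration, on a different route from the package
# code they check.

# --- stub likelihood provider ----------------------------------------------
# A likelihood table keyed by the sorted member set, so BHC machinery can be
# exercised with fixed H1 values and no GP involved.
memb_key <- function(members) paste(sort(members), collapse = ",")

stub_loglik <- function(tbl) {
  function(members, init = NULL) {
    key <- memb_key(members)
    if (is.null(tbl[[key]])) stop("stub has no value for {", key, "}")
    list(logLik = tbl[[key]], hyper = gp_hyper(1, 1, 0.1), warn = FALSE)
  }
}

# random H1 table over every non-empty subset of 1..n
random_h1_table <- function(n, sd = 3) {
  tbl <- list()
  for (size in seq_len(n)) {
    for (rows in utils::combn(n, size, simplify = FALSE)) {
      tbl[[memb_key(rows)]] <- rnorm(1, sd = sd)
    }
  }
  tbl
}

# build a bhc_node tree from a nested structure: a leaf is an integer, an
# internal node is list(left, right); returns the root bhc_node
stub_tree <- function(shape, alpha, tbl) {
  ll <- stub_loglik(tbl)
  build <- function(s) {
    if (!is.list(s)) return(tsbhc:::new_leaf_node(s, alpha, ll(s)))
    merge_posterior(build(s[[1]]), build(s[[2]]), alpha, ll)
  }
  build(shape)
}

# --- exhaustive tree-consistent-partition oracle ---------------------------
# Enumerates every partition obtainable by cutting the (sub)tree; each
# partition is a list of sorted integer vectors.
tc_partitions <- function(shape) {
  members <- sort(unlist(shape))
  if (!is.list(shape)) return(list(list(members)))
  combos <- list()
  for (pl in tc_partitions(shape[[1]]))
    for (pr in tc_partitions(shape[[2]]))
      combos[[length(combos) + 1L]] <- c(pl, pr)
  c(list(list(members)), combos)
}

# d_k = sum over tree-consistent partitions of alpha^{#blocks} prod Gamma(n_b)
enum_d <- function(shape, alpha) {
  sum(vapply(tc_partitions(shape), function(v) {
    alpha^length(v) * prod(gamma(lengths(v)))
  }, 1))
}

# p(D|T_k) = sum over tree-consistent partitions of
#   [alpha^{#blocks} prod Gamma(n_b) / d_k] * prod_b p(D_b|H1)
enum_pT <- function(shape, alpha, tbl) {
  d <- enum_d(shape, alpha)
  sum(vapply(tc_partitions(shape), function(v) {
    w <- alpha^length(v) * prod(gamma(lengths(v))) / d
    w * prod(vapply(v, function(b) exp(tbl[[memb_key(b)]]), 1))
  }, 1))
}

# --- brute-force adjusted Rand index ---------------------------------------
# Pair-counting route (contingency table never formed): classify every
# unordered pair as together/apart in each partition, then use the
# pair-count form of the index.
ari_bruteforce <- function(p1, p2) {
  n <- length(p1)
  a <- b <- cc <- d <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      s1 <- p1[i] == p1[j]; s2 <- p2[i] == p2[j]
      if (s1 && s2) a <- a + 1
      else if (s1 && !s2) b <- b + 1
      else if (!s1 && s2) cc <- cc + 1
      else d <- d + 1
    }
  }
  denom <- (a + b) * (b + d) + (a + cc) * (cc + d)
  if (denom == 0) return(0)
  2 * (a * d - b * cc) / denom
}

# small random expression fixture
random_expr <- function(n, q, seed = 1) {
  set.seed(seed)
  ts_expr(matrix(rnorm(n * q), n, q), times = seq_len(q) - 1)
}
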