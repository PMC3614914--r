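# GP marginal likelihood layer: kernel, stacked covariance, fast-vs-naive
# equivalence, gradients, optimiser behaviour.

test_that("se_covariance matches element-wise evaluation of the kernel", {
  times <- c(0, 1, 2)
  h <- gp_hyper(1, 1, 0.1)
  K <- se_covariance(times, h, include_noise = TRUE)
  # scalar oracle, entry by entry
  for (i in 1:3) {
    for (j in 1:3) {
      expect_equal(K[i, j],
                   exp(-(times[i] - times[j])^2 / 2) + 0.1 * (i == j),
                   tolerance = 1e-12)
    }
  }
  expect_equal(K, t(K))
  # diagonal = sf2 + sn2; distant points decay to ~0 off-diagonal
  h2 <- gp_hyper(2.5, 0.3, 0.7)
  K2 <- se_covariance(c(0, 100), h2)
  expect_equal(diag(K2), rep(2.5 + 0.7, 2))
  expect_lt(abs(K2[1, 2]), 1e-300)
  # no-noise variant drops the delta term only
  expect_equal(se_covariance(times, h, include_noise = FALSE),
               K - diag(0.1, 3))
})

test_that("invalid hyperparameters and grids are rejected", {
  expect_error(gp_hyper(-1, 1, 1), "positive")
  expect_error(gp_hyper(1, 0, 1), "positive")
  expect_error(se_covariance(c(0, 0, 1), gp_hyper()), "duplicate")
  expect_error(se_covariance(c(3, 1), gp_hyper()), "increasing")
})

test_that("build_full_covariance has the stated block structure", {
  Kf <- se_covariance(0:2, gp_hyper(1, 1, 1), include_noise = FALSE)
  # n = 1: single block plus noise
  expect_equal(build_full_covariance(1, Kf, 0.2), Kf + diag(0.2, 3))
  # n = 2, q = 1 Kronecker expansion by hand
  expect_equal(build_full_covariance(2, matrix(3), 0.5),
               matrix(c(3.5, 3, 3, 3.5), 2))
  # random PSD K_f, n = 3: result is PSD
  set.seed(7)
  A <- matrix(rnorm(4), 2)
  K <- crossprod(A)
  C <- build_full_covariance(3, K, 0.3)
  expect_true(all(eigen(C, symmetric = TRUE, only.values = TRUE)$values > 0))
  expect_error(build_full_covariance(3, K, -1), "positive")
})

test_that("naive marginal reproduces closed forms at n = q = 1", {
  # y = 0, total variance 1 -> standard normal log-density at 0
  expect_equal(log_marginal_naive(matrix(0), 0, gp_hyper(0.5, 1, 0.5)),
               -0.5 * log(2 * pi), tolerance = 1e-7)
  expect_equal(log_marginal_naive(matrix(1), 0, gp_hyper(0.5, 1, 0.5)),
               -0.5 * log(2 * pi) - 0.5, tolerance = 1e-7)
})

test_that("naive marginal agrees with an independently coded MVN density", {
  set.seed(11)
  Y <- matrix(rnorm(6), 2, 3)
  times <- c(0, 0.5, 2)
  h <- gp_hyper(1.3, 0.9, 0.25)
  # independent route: explicit inverse and determinant(), gene-major vec
  C <- build_full_covariance(2, se_covariance(times, h, FALSE),
                             h[["noise_variance"]])
  diag(C) <- diag(C) + 1e-8
  y <- as.vector(t(Y))
  ld <- as.numeric(determinant(C, logarithm = TRUE)$modulus)
  ref <- -0.5 * (length(y) * log(2 * pi) + ld + y %*% solve(C, y))
  expect_equal(log_marginal_naive(Y, times, h), as.numeric(ref),
               tolerance = 1e-10)
})

test_that("fast path equals the naive oracle on random instances", {
  set.seed(1)
  for (k in 1:60) {
    n <- sample(1:6, 1)
    q <- sample(2:8, 1)
    Y <- matrix(rnorm(n * q), n, q)
    times <- sort(runif(q, 0, 10))
    h <- gp_hyper(exp(runif(1, -1, 1)), exp(runif(1, -1, 1)),
                  exp(runif(1, -2, 0)))
    naive <- log_marginal_naive(Y, times, h)
    fast <- log_marginal_fast(Y, times, h)
    expect_equal(fast, naive, tolerance = 1e-8)
  }
})

test_that("signal-variance -> 0 limit is the iid noise model", {
  set.seed(2)
  Y <- matrix(rnorm(15), 3, 5)
  h <- gp_hyper(1e-12, 1, 0.4)
  iid <- sum(dnorm(Y, sd = sqrt(0.4 + 1e-8), log = TRUE))
  expect_equal(log_marginal_fast(Y, 0:4, h), iid, tolerance = 1e-6)
})

test_that("analytic gradient matches central differences", {
  set.seed(3)
  Y <- matrix(rnorm(20), 4, 5)
  times <- 0:4
  par <- log(c(0.7, 1.8, 0.3))
  g <- log_marginal_fast(Y, times,
                         gp_hyper(exp(par[1]), exp(par[2]), exp(par[3])),
                         want_grad = TRUE)
  eps <- 1e-5
  num <- vapply(1:3, function(k) {
    e <- replace(rep(0, 3), k, eps)
    up <- exp(par + e); dn <- exp(par - e)
    (log_marginal_fast(Y, times, gp_hyper(up[1], up[2], up[3])) -
     log_marginal_fast(Y, times, gp_hyper(dn[1], dn[2], dn[3]))) / (2 * eps)
  }, 1)
  expect_equal(g$grad, num, tolerance = 1e-5)
})

test_that("duplicate-gene degenerate input stays finite", {
  set.seed(4)
  y <- rnorm(6)
  Y <- rbind(y, y, y)  # exact duplicates, near-zero-noise hyper
  v <- log_marginal_fast(Y, 0:5, gp_hyper(1, 1, 1e-6))
  expect_true(is.finite(v))
})

test_that("row normalisation leaves mean 0 and sd 1 exactly", {
  set.seed(5)
  x <- ts_expr(matrix(rnorm(200, mean = 7, sd = 3), 20, 10), times = 0:9)
  expect_true(all(abs(rowMeans(x$values)) < 1e-10))
  expect_true(all(abs(apply(x$values, 1, sd) - 1) < 1e-10))
  expect_error(ts_expr(matrix(1, 2, 4), 0:3), "constant")
})

test_that("optimiser ascends and is idempotent at an optimum", {
  set.seed(6)
  sim <- generate_synthetic(synthetic_config(1, 30, times = 0:9,
                                             hyper = gp_hyper(1, 2, 0.1),
                                             seed = 6))
  Y <- sim$expr$values
  init <- default_gp_init(Y, 0:9)
  fit <- optimise_hyperparams(Y, 0:9, init = init)
  expect_gte(fit$logLik, log_marginal_fast(Y, 0:9, init))
  # restarting at the optimum reproduces the same optimum
  fit2 <- optimise_hyperparams(Y, 0:9, init = fit$hyper)
  expect_equal(fit2$logLik, fit$logLik, tolerance = 1e-6)
  # ascent also on structureless pure-noise data
  set.seed(7)
  N <- matrix(rnorm(50), 5, 10)
  initN <- default_gp_init(N, 0:9)
  fitN <- optimise_hyperparams(N, 0:9, init = initN)
  expect_gte(fitN$logLik, log_marginal_fast(N, 0:9, initN))
  expect_false(fit$warn)
})

test_that("numerical-gradient mode agrees with analytic mode", {
  set.seed(8)
  Y <- matrix(rnorm(40), 4, 10)
  fa <- optimise_hyperparams(Y, 0:9)
  fn <- optimise_hyperparams(Y, 0:9, gradient = "numerical")
  expect_equal(fa$logLik, fn$logLik, tolerance = 1e-4)
})

test_that("gp evaluation counter counts likelihood evaluations", {
  reset_gp_eval_count()
  expect_identical(gp_eval_count(), 0L)
  log_marginal_fast(matrix(rnorm(4), 1), 0:3, gp_hyper())
  log_marginal_fast(matrix(rnorm(4), 1), 0:3, gp_hyper())
  expect_identical(gp_eval_count(), 2L)
  reset_gp_eval_count()
  expect_identical(gp_eval_count(), 0L)
})
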