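#' Gaussian-process hyperparameters for the squared-exponential model
#'
#' @param signal_variance positive; marginal variance of the latent function
#'   (sigma_f^2, in units of normalised expression variance).
#' @param length_scale positive; characteristic time scale l of the kernel, in
#'   the units of the time grid.
#' @param noise_variance positive; iid observation noise variance sigma_n^2.
#' @return numeric vector of class `gp_hyper` with the three components.
#' @export
gp_hyper <- function(signal_variance = 1, length_scale = 1,
                     noise_variance = 0.1) {
  h <- c(signal_variance = as.numeric(signal_variance),
         length_scale = as.numeric(length_scale),
         noise_variance = as.numeric(noise_variance))
  if (anyNA(h) || any(h <= 0) || any(!is.finite(h)))
    stop("all GP hyperparameters must be strictly positive and finite")
  structure(h, class = "gp_hyper")
}

as_gp_hyper <- function(h) {
  if (inherits(h, "gp_hyper")) return(h)
  gp_hyper(h[[1L]], h[[2L]], h[[3L]])
}

#' Squared-exponential covariance matrix on a time grid
#'
#' k(t, t') = sigma_f^2 exp(-(t - t')^2 / (2 l^2)), with sigma_n^2 added on
#' the diagonal (Kronecker delta) when `include_noise = TRUE`.
#'
#' @param times strictly increasing numeric time grid.
#' @param hyper a [gp_hyper()] object.
#' @param include_noise add the noise variance to the diagonal?
#' @return q x q symmetric covariance matrix.
#' @export
se_covariance <- function(times, hyper, include_noise = TRUE) {
  validate_time_grid(times)
  hyper <- as_gp_hyper(hyper)
  d <- outer(times, times, "-")
  K <- hyper[["signal_variance"]] *
    exp(-d^2 / (2 * hyper[["length_scale"]]^2))
  if (include_noise) diag(K) <- diag(K) + hyper[["noise_variance"]]
  K
}

#' Full stacked covariance for a cluster sharing one latent function
#'
#' With all genes in a cluster modelled as noisy observations of a single GP
#' draw, the covariance of the stacked nq-vector (gene-major order) is
#' (1_n 1_n') (x) K_f + sigma_n^2 I.
#'
#' @param n_genes number of genes in the cluster.
#' @param K_f q x q noise-free kernel matrix.
#' @param noise_variance positive observation-noise variance.
#' @return nq x nq covariance matrix. Intended for small problems; the
#'   clustering engine never materialises it (see [log_marginal_fast()]).
#' @export
build_full_covariance <- function(n_genes, K_f, noise_variance) {
  if (n_genes < 1L) stop("n_genes must be >= 1")
  if (noise_variance <= 0) stop("noise_variance must be positive")
  q <- nrow(K_f)
  C <- kronecker(matrix(1, n_genes, n_genes), K_f)
  diag(C) <- diag(C) + noise_variance
  C
}

#' GP marginal log-likelihood, dense reference implementation
#'
#' Evaluates log N(vec(Y); 0, C) with C from [build_full_covariance()] by
#' direct Cholesky factorisation of the full nq x nq matrix. This is the
#' oracle against which [log_marginal_fast()] is validated; cost O(n^3 q^3),
#' so only suitable for small clusters.
#'
#' @param Y n x q matrix of (normalised) observations, or a `ts_expr`.
#' @param times time grid (ignored when `Y` is a `ts_expr`).
#' @param hyper a [gp_hyper()] object.
#' @return scalar log-likelihood.
#' @export
log_marginal_naive <- function(Y, times, hyper) {
  if (inherits(Y, "ts_expr")) { times <- Y$times; Y <- Y$values }
  Y <- as.matrix(Y)
  hyper <- as_gp_hyper(hyper)
  Kf <- se_covariance(times, hyper, include_noise = FALSE)
  C <- build_full_covariance(nrow(Y), Kf, hyper[["noise_variance"]])
  diag(C) <- diag(C) + 1e-8  # jitter, matches the fast path
  y <- as.vector(t(Y))  # gene-major stacking
  L <- tryCatch(t(chol(C)), error = function(e)
    stop("covariance not positive definite after jitter: ",
         conditionMessage(e)))
  z <- forwardsolve(L, y)
  -0.5 * (length(y) * log(2 * pi)) - sum(log(diag(L))) - 0.5 * sum(z^2)
}

#' GP marginal log-likelihood, block-structure accelerated
#'
#' Returns the same value as [log_marginal_naive()] but exploits the shared
#' latent-function structure: the stacked covariance acts as
#' n K_f + sigma_n^2 I on the across-gene mean component and as sigma_n^2 I
#' on the n - 1 orthogonal components, so the computation is O(q^3 + n q) and
#' the nq x nq matrix is never formed. Each call increments the
#' [gp_eval_count()] work counter.
#'
#' @inheritParams log_marginal_naive
#' @param want_grad also return the gradient with respect to
#'   (log sigma_f^2, log l, log sigma_n^2)?
#' @return scalar log-likelihood, or (with `want_grad`) a list with `value`
#'   and 3-vector `grad`.
#' @export
log_marginal_fast <- function(Y, times, hyper, want_grad = FALSE) {
  if (inherits(Y, "ts_expr")) { times <- Y$times; Y <- Y$values }
  Y <- as.matrix(Y)
  hyper <- as_gp_hyper(hyper)
  the$gp_evals <- the$gp_evals + 1L
  res <- gp_logmarg_se_cpp(Y, as.numeric(times),
                           log(hyper[["signal_variance"]]),
                           log(hyper[["length_scale"]]),
                           log(hyper[["noise_variance"]]),
                           want_grad)
  if (want_grad) res else res$value
}

# log-space objective used by the optimiser; par = log(sf2, l, sn2)
gp_objective <- function(par, Y, times, want_grad = TRUE) {
  the$gp_evals <- the$gp_evals + 1L
  gp_logmarg_se_cpp(Y, times, par[1L], par[2L], par[3L], want_grad)
}

#' Default hyperparameter initialisation
#'
#' Unit signal variance (natural for row-normalised data), length-scale set
#' to half the grid span, and noise variance at half the sample variance of
#' the pooled data.
#'
#' @inheritParams log_marginal_naive
#' @return a [gp_hyper()] object.
#' @export
default_gp_init <- function(Y, times) {
  if (inherits(Y, "ts_expr")) { times <- Y$times; Y <- Y$values }
  span <- diff(range(times))
  ls <- if (span > 0) span / 2 else 1
  nv <- 0.5 * var(as.vector(Y))
  if (!is.finite(nv) || nv <= 0) nv <- 0.5
  gp_hyper(1, ls, nv)
}

#' Optimise GP hyperparameters by quasi-Newton ascent
#'
#' Maximises [log_marginal_fast()] over (log sigma_f^2, log l, log sigma_n^2)
#' with L-BFGS-B inside a log-space box. Analytic gradients are the default;
#' `gradient = "numerical"` falls back to the optimiser's internal finite
#' differences. The returned log-likelihood is never below the value at the
#' initial point, and the optimiser never raises: non-convergence returns the
#' best iterate with `warn = TRUE`.
#'
#' @inheritParams log_marginal_naive
#' @param init starting [gp_hyper()]; defaults to [default_gp_init()].
#' @param bounds length-2 numeric, log-space box applied to all three
#'   parameters (default `c(-10, 10)`).
#' @param gradient `"analytic"` (default) or `"numerical"`.
#' @param control passed to [stats::optim()] (method L-BFGS-B).
#' @return list with `hyper` (optimised [gp_hyper()]), `logLik` (value at the
#'   optimum), `warn` (logical convergence flag), `counts`.
#' @export
optimise_hyperparams <- function(Y, times, init = NULL,
                                 bounds = c(-10, 10),
                                 gradient = c("analytic", "numerical"),
                                 control = list()) {
  if (inherits(Y, "ts_expr")) { times <- Y$times; Y <- Y$values }
  Y <- as.matrix(Y)
  times <- as.numeric(times)
  gradient <- match.arg(gradient)
  if (is.null(init)) init <- default_gp_init(Y, times)
  init <- as_gp_hyper(init)
  par0 <- pmin(pmax(log(unclass(init)), bounds[1L]), bounds[2L])

  # cache so optim's separate fn/gr calls at the same point cost one eval
  cache <- new.env(parent = emptyenv())
  fn <- function(par) {
    r <- gp_objective(par, Y, times, want_grad = (gradient == "analytic"))
    cache$par <- par; cache$res <- r
    if (!is.finite(r$value)) return(1e10)
    -r$value
  }
  gr <- if (gradient == "analytic") function(par) {
    if (!is.null(cache$par) && identical(cache$par, par)) r <- cache$res
    else { r <- gp_objective(par, Y, times, TRUE); cache$par <- par; cache$res <- r }
    if (!is.finite(r$value) || any(!is.finite(r$grad))) return(rep(0, 3L))
    -r$grad
  } else NULL

  f0 <- -fn(par0)
  fit <- tryCatch(
    optim(par0, fn, gr, method = "L-BFGS-B",
          lower = bounds[1L], upper = bounds[2L],
          control = modifyList(list(maxit = 200L), control)),
    error = function(e) NULL)

  warn <- is.null(fit) || fit$convergence != 0L
  if (is.null(fit) || -fit$value < f0) {
    par <- par0; val <- f0
  } else {
    par <- fit$par; val <- -fit$value
  }
  list(hyper = gp_hyper(exp(par[1L]), exp(par[2L]), exp(par[3L])),
       logLik = val, warn = warn,
       counts = if (is.null(fit)) c(`function` = 1L) else fit$counts)
}
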