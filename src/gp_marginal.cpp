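// GP marginal likelihood of n time series hypothesised to share one latent
// function, sampled on a common grid of q time points.
//
// Covariance over the stacked nq-vector is (1_n 1_n^T) (x) K_f + sn2 * I.
// Because every off-diagonal block equals K_f, the matrix acts as
//   A = n K_f + sn2 I_q   on the across-gene mean component, and
//   sn2 I                 on the (n-1) orthogonal components,
// so the log-determinant and quadratic form reduce to q x q operations:
// cost O(q^3 + n q) instead of O(n^3 q^3).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

static const double JITTER = 1e-8;

// value (and gradient w.r.t. log sf2, log l, log sn2) of the log marginal.
// Y: n x q matrix of observations (rows = genes); t: q time points.
// [[Rcpp::export]]
Rcpp::List gp_logmarg_se_cpp(const arma::mat& Y, const arma::vec& t,
                             double log_sf2, double log_l, double log_sn2,
                             bool want_grad) {
  const double sf2 = std::exp(log_sf2);
  const double l   = std::exp(log_l);
  const double sn2 = std::exp(log_sn2);
  const arma::uword n = Y.n_rows, q = Y.n_cols;

  arma::mat D2(q, q);
  for (arma::uword i = 0; i < q; ++i)
    for (arma::uword j = 0; j < q; ++j) {
      const double d = t(i) - t(j);
      D2(i, j) = d * d;
    }
  const arma::mat Kf = sf2 * arma::exp(-D2 / (2.0 * l * l));

  // jitter is folded into the noise term so the reduction matches the dense
  // reference (which jitters the whole nq diagonal) to machine precision
  const double sn2j = sn2 + JITTER;
  arma::mat A = double(n) * Kf;
  A.diag() += sn2j;

  arma::mat L;
  if (!arma::chol(L, A, "lower"))
    Rcpp::stop("covariance not positive definite after jitter");

  // s = projection of the data onto the across-gene mean direction
  const arma::vec s = std::sqrt(double(n)) *
    arma::conv_to<arma::vec>::from(arma::mean(Y, 0));
  const double Stot = arma::accu(Y % Y);

  const arma::vec alpha = arma::solve(arma::trimatu(L.t()),
                          arma::solve(arma::trimatl(L), s));
  const double logdetA = 2.0 * arma::accu(arma::log(L.diag()));
  const double ss = arma::dot(s, s);
  const double resid = Stot - ss;  // >= 0 up to rounding
  const double quad = arma::dot(s, alpha) + resid / sn2j;
  const double logdet = logdetA + double((n - 1) * q) * std::log(sn2j);
  const double val = -0.5 * (double(n * q) * std::log(2.0 * M_PI) + logdet + quad);

  if (!want_grad)
    return Rcpp::List::create(Rcpp::Named("value") = val);

  arma::mat Ainv = arma::inv_sympd(A);

  // kernel-parameter derivatives: dK/dlog(sf2) = Kf, dK/dlog(l) = Kf % (D2/l^2)
  const arma::mat dK_lsf2 = Kf;
  const arma::mat dK_ll   = Kf % (D2 / (l * l));

  auto kern_grad = [&](const arma::mat& dK) -> double {
    const arma::mat B = double(n) * dK;
    const double tr = arma::accu(Ainv % B);  // trace(Ainv B), both symmetric
    const double qf = arma::as_scalar(alpha.t() * B * alpha);
    return -0.5 * (tr - qf);
  };

  const double g_lsf2 = kern_grad(dK_lsf2);
  const double g_ll   = kern_grad(dK_ll);
  const double g_lsn2 = -0.5 * (sn2 * arma::trace(Ainv)
                                + double((n - 1) * q) * (sn2 / sn2j)
                                - sn2 * arma::dot(alpha, alpha)
                                - resid * sn2 / (sn2j * sn2j));

  return Rcpp::List::create(
    Rcpp::Named("value") = val,
    Rcpp::Named("grad")  = Rcpp::NumericVector::create(g_lsf2, g_ll, g_lsn2));
}
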