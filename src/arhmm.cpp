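#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Forward-filter backward-sample for one label sequence.
// loglik: T x K per-frame observation log-likelihoods
// trans:  K x K row-stochastic transition matrix
// init:   K initial-state probabilities
// Returns 1-based state labels of length T. Uses R's RNG (seed-reproducible).
// [[Rcpp::export]]
IntegerVector ffbs_sample(const arma::mat& loglik, const arma::mat& trans,
                          const arma::vec& init) {
  const int T = loglik.n_rows, K = loglik.n_cols;
  arma::mat alpha(T, K);

  arma::rowvec ll0 = loglik.row(0);
  arma::rowvec a = init.t() % arma::exp(ll0 - ll0.max());
  double s = arma::accu(a);
  if (s <= 0) stop("numerical underflow in forward filter at frame 1");
  alpha.row(0) = a / s;

  for (int t = 1; t < T; ++t) {
    arma::rowvec pred = alpha.row(t - 1) * trans;
    arma::rowvec ll = loglik.row(t);
    a = pred % arma::exp(ll - ll.max());
    s = arma::accu(a);
    if (s <= 0) stop("numerical underflow in forward filter");
    alpha.row(t) = a / s;
  }

  IntegerVector z(T);
  arma::rowvec w = alpha.row(T - 1);
  double u = R::unif_rand() * arma::accu(w);
  int k = 0;
  for (double c = w(0); c < u && k < K - 1; c += w(++k)) {}
  z[T - 1] = k + 1;

  for (int t = T - 2; t >= 0; --t) {
    w = alpha.row(t) % trans.col(z[t + 1] - 1).t();
    double tot = arma::accu(w);
    if (tot <= 0) stop("numerical underflow in backward sampler");
    u = R::unif_rand() * tot;
    k = 0;
    for (double c = w(0); c < u && k < K - 1; c += w(++k)) {}
    z[t] = k + 1;
  }
  return z;
}

// Per-state Gaussian AR observation log-likelihoods.
// Y: T x d responses; X: T x p regressors; Beta: cube d x p x K;
// Sigma: cube d x d x K. Returns T x K.
// [[Rcpp::export]]
arma::mat arhmm_obs_loglik(const arma::mat& Y, const arma::mat& X,
                           const arma::cube& Beta, const arma::cube& Sigma) {
  const int T = Y.n_rows, d = Y.n_cols, K = Beta.n_slices;
  arma::mat out(T, K);
  const double c0 = -0.5 * d * std::log(2.0 * M_PI);
  for (int k = 0; k < K; ++k) {
    arma::mat U = arma::chol(Sigma.slice(k));  // upper: Sigma = U' U
    double logdet = 2.0 * arma::accu(arma::log(U.diag()));
    arma::mat res = Y - X * Beta.slice(k).t();           // T x d
    arma::mat V = arma::solve(arma::trimatl(U.t()), res.t());  // d x T
    out.col(k) = c0 - 0.5 * logdet - 0.5 * arma::sum(arma::square(V), 0).t();
  }
  return out;
}
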