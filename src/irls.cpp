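// Iteratively reweighted least squares for logistic regression.
// Fisher scoring on the p x p normal equations; convergence on relative
// deviance change < epsilon within maxit iterations. Returns the
// coefficient vector, the Wald covariance (X' W X)^-1 at the optimum, and
// a convergence flag; rank deficiency reports converged = false.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
Rcpp::List irls_logistic_cpp(const arma::mat& X, const arma::vec& y,
                             const double epsilon, const int maxit) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  arma::vec mu = (y + 0.5) / 2.0;
  arma::vec eta = arma::log(mu / (1.0 - mu));
  arma::vec beta(p, arma::fill::zeros);
  arma::mat XtWX(p, p, arma::fill::zeros);
  double dev = arma::datum::inf;
  bool converged = false;

  for (int iter = 0; iter < maxit; ++iter) {
    arma::vec w = mu % (1.0 - mu);
    w.clamp(1e-10, arma::datum::inf);
    arma::vec z = eta + (y - mu) / w;
    arma::mat Xw = X.each_col() % w;
    XtWX = X.t() * Xw;
    arma::vec Xtwz = X.t() * (w % z);
    bool ok = arma::solve(beta, XtWX, Xtwz,
                          arma::solve_opts::likely_sympd + arma::solve_opts::no_approx);
    if (!ok) {
      return Rcpp::List::create(Rcpp::Named("coefficients") = beta,
                                Rcpp::Named("cov") = R_NilValue,
                                Rcpp::Named("deviance") = dev,
                                Rcpp::Named("converged") = false);
    }
    eta = X * beta;
    mu = 1.0 / (1.0 + arma::exp(-eta));
    mu.clamp(1e-12, 1.0 - 1e-12);
    double dev_new = 0.0;
    for (arma::uword i = 0; i < n; ++i) {
      dev_new += (y[i] == 1.0) ? std::log(mu[i]) : std::log1p(-mu[i]);
    }
    dev_new *= -2.0;
    const bool done = std::isfinite(dev_new) &&
        std::abs(dev_new - dev) / (std::abs(dev_new) + 0.1) < epsilon;
    dev = dev_new;
    if (done) {
      converged = true;
      break;
    }
  }
  arma::mat cov(p, p);
  bool okc = arma::inv_sympd(cov, XtWX);
  return Rcpp::List::create(
      Rcpp::Named("coefficients") = beta,
      Rcpp::Named("cov") = okc ? Rcpp::wrap(cov) : R_NilValue,
      Rcpp::Named("deviance") = dev,
      Rcpp::Named("converged") = converged && okc);
}
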