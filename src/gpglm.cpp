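// Gamma-Poisson (negative binomial) GLM machinery: ridge-penalized IRLS,
// log-likelihood evaluation and the Cox-Reid adjustment term.
// Dispersion parameterization: var = mu + alpha * mu^2; alpha == 0 is Poisson.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double ETA_MAX = 30.0;

static double gp_ll(const arma::vec& y, const arma::vec& mu, double alpha) {
  double ll = 0.0;
  const int n = y.n_elem;
  if (alpha < 1e-12) {
    for (int i = 0; i < n; ++i)
      ll += y[i] * std::log(mu[i]) - mu[i] - std::lgamma(y[i] + 1.0);
  } else {
    const double r = 1.0 / alpha;
    const double lgr = std::lgamma(r);
    for (int i = 0; i < n; ++i) {
      ll += std::lgamma(y[i] + r) - lgr - std::lgamma(y[i] + 1.0)
          + r * std::log(r / (r + mu[i]))
          + y[i] * std::log(mu[i] / (r + mu[i]));
    }
  }
  return ll;
}

// [[Rcpp::export]]
double cppGPLogLik(const arma::vec& y, const arma::vec& mu, double alpha) {
  return gp_ll(y, mu, alpha);
}

// 0.5 * log det( X' W X ) with W the GLM working weights mu/(1+alpha*mu).
// [[Rcpp::export]]
double cppCoxReidTerm(const arma::mat& X, const arma::vec& mu, double alpha) {
  arma::vec w = mu / (1.0 + alpha * mu);
  arma::mat XtWX = X.t() * (X.each_col() % w);
  double val, sign;
  arma::log_det(val, sign, XtWX);
  return 0.5 * val;
}

// Ridge-penalized IRLS for the GP GLM.
//   minimize  -loglik(beta) + 0.5 * sum_k lambda_k beta_k^2
// lambda_k = 0 leaves coefficient k unpenalized. Offsets enter the linear
// predictor additively (log size factors). Step-halving guards monotonicity
// of the penalized likelihood.
// [[Rcpp::export]]
List cppGPIRLS(const arma::mat& X, const arma::vec& y, const arma::vec& offset,
               double alpha, const arma::vec& lambda,
               double tol = 1e-8, int maxit = 100) {
  const int p = X.n_cols;
  arma::vec beta(p, arma::fill::zeros);
  arma::mat Lam = arma::diagmat(lambda);

  arma::vec mu0 = y + 0.5;
  arma::vec eta = arma::log(mu0);
  // initialize by one unweighted LS fit of log(y + 0.5) - offset
  {
    arma::vec z0 = eta - offset;
    arma::mat A = X.t() * X + Lam + 1e-12 * arma::eye(p, p);
    beta = arma::solve(A, X.t() * z0, arma::solve_opts::likely_sympd);
  }

  auto predict = [&](const arma::vec& b, arma::vec& eta_out, arma::vec& mu_out) {
    eta_out = X * b + offset;
    eta_out = arma::clamp(eta_out, -ETA_MAX, ETA_MAX);
    mu_out = arma::exp(eta_out);
  };

  arma::vec mu;
  predict(beta, eta, mu);
  double pll = gp_ll(y, mu, alpha) - 0.5 * arma::dot(lambda, beta % beta);

  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= maxit; ++iter) {
    arma::vec w = mu / (1.0 + alpha * mu);
    arma::vec z = (eta - offset) + (y - mu) / mu;
    arma::mat A = X.t() * (X.each_col() % w) + Lam;
    A.diag() += 1e-12;
    arma::vec rhs = X.t() * (w % z);
    arma::vec beta_new;
    bool ok = arma::solve(beta_new, A, rhs, arma::solve_opts::likely_sympd);
    if (!ok) break;

    // step halving on the penalized log-likelihood
    arma::vec eta_new, mu_new;
    double step = 1.0;
    double pll_new = -arma::datum::inf;
    arma::vec cand = beta_new;
    for (int h = 0; h < 8; ++h) {
      cand = beta + step * (beta_new - beta);
      predict(cand, eta_new, mu_new);
      pll_new = gp_ll(y, mu_new, alpha) - 0.5 * arma::dot(lambda, cand % cand);
      if (pll_new >= pll - 1e-12) break;
      step *= 0.5;
    }
    double delta = arma::abs(cand - beta).max();
    beta = cand;
    eta = eta_new;
    mu = mu_new;
    pll = pll_new;
    if (delta < tol) { converged = true; break; }
  }

  arma::vec w = mu / (1.0 + alpha * mu);
  arma::mat A = X.t() * (X.each_col() % w) + Lam;
  A.diag() += 1e-12;
  arma::vec covdiag(p); covdiag.fill(NA_REAL);
  arma::mat Ainv;
  if (arma::inv_sympd(Ainv, A)) covdiag = Ainv.diag();

  return List::create(
    _["beta"] = beta,
    _["mu"] = mu,
    _["loglik"] = gp_ll(y, mu, alpha),
    _["penloglik"] = pll,
    _["converged"] = converged,
    _["iter"] = iter,
    _["covDiag"] = covdiag);
}
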