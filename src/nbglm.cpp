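#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Per-feature negative-binomial log-linear fit by iteratively reweighted
// least squares with a method-of-moments dispersion, for a shared design.
//
// Model: y_ij ~ NB(mu_ij, alpha_i), mu_ij = s_j * exp(x_j' beta_i),
// Var = mu + alpha * mu^2. The dispersion is estimated from the Poisson
// (alpha = 0) fit residuals: alpha = max(0, sum((y-mu)^2 - mu) / sum(mu^2)),
// then the mean model is refit with NB weights w = mu / (1 + alpha mu) and a
// Wald statistic formed for one coefficient.
//
// status: 0 = ok, 1 = not converged, 2 = untestable (all-zero feature).
// [[Rcpp::export(name = ".nb_wald_cpp")]]
List nb_wald_cpp(const arma::mat& Y,       // features x samples
                 const arma::mat& X,       // samples x p
                 const arma::vec& offset,  // log size factors, length samples
                 const int coef,           // 0-based column of X to test
                 const int maxit = 50,
                 const double tol = 1e-8) {
  const arma::uword G = Y.n_rows, N = Y.n_cols, P = X.n_cols;
  if (X.n_rows != N || offset.n_elem != N)
    stop("design/offset dimensions do not match the count matrix");
  if (coef < 0 || (arma::uword)coef >= P) stop("coef index out of range");

  arma::vec est(G, arma::fill::zeros), se(G), alpha(G, arma::fill::zeros);
  arma::vec phi(G, arma::fill::ones);
  se.fill(NA_REAL);
  arma::ivec status(G, arma::fill::zeros);
  arma::ivec iters(G, arma::fill::zeros);

  arma::vec y(N), eta(N), mu(N), w(N), z(N), beta(P), betaNew(P);
  arma::mat XtWX(P, P);

  for (arma::uword g = 0; g < G; ++g) {
    y = Y.row(g).t();
    if (arma::all(y <= 0)) {
      status(g) = 2;
      continue;
    }
    // init: least squares on log((y + 0.5) / s)
    arma::vec yl = arma::log(y + 0.5) - offset;
    beta = arma::solve(X, yl);

    // one IRLS pass with a given alpha; returns convergence flag
    auto irls = [&](double a, int& used) -> bool {
      bool conv = false;
      for (int it = 0; it < maxit; ++it) {
        eta = X * beta + offset;
        eta = arma::clamp(eta, -30.0, 30.0);
        mu = arma::exp(eta);
        w = mu / (1.0 + a * mu);
        z = (eta - offset) + (y - mu) / mu;
        XtWX = X.t() * (X.each_col() % w);
        bool ok = arma::solve(betaNew, XtWX, X.t() * (w % z),
                              arma::solve_opts::no_approx);
        if (!ok) return false;
        double delta = arma::abs(betaNew - beta).max();
        beta = betaNew;
        used = it + 1;
        if (delta < tol) {
          conv = true;
          break;
        }
      }
      return conv;
    };

    int used = 0;
    bool convP = irls(0.0, used);
    // moments dispersion from the Poisson fit, with the residual
    // degrees-of-freedom correction n / (n - p) on the squared residuals
    eta = arma::clamp(X * beta + offset, -30.0, 30.0);
    mu = arma::exp(eta);
    const double dfc = (double)N / std::max(1.0, (double)N - (double)P);
    double a = arma::accu(dfc * arma::square(y - mu) - mu) /
               arma::accu(arma::square(mu));
    if (!std::isfinite(a) || a < 0.0) a = 0.0;
    alpha(g) = a;

    bool convN = irls(a, used);
    iters(g) = used;
    eta = arma::clamp(X * beta + offset, -30.0, 30.0);
    mu = arma::exp(eta);
    w = mu / (1.0 + a * mu);
    XtWX = X.t() * (X.each_col() % w);
    arma::mat cov;
    bool okc = arma::inv_sympd(cov, XtWX);
    if (!okc) okc = arma::inv(cov, XtWX);
    if (!okc || !(convP || convN)) {
      status(g) = 1;
      est(g) = 0.0;
      continue;
    }
    if (!convN) status(g) = 1;
    est(g) = beta(coef);
    se(g) = std::sqrt(cov(coef, coef));
    // quasi-likelihood dispersion: Pearson chi-square over residual df on
    // the NB working variance, floored at 1 (guards the Wald tail against
    // under-estimated dispersion)
    if (N > P) {
      double x2 = arma::accu(arma::square(y - mu) /
                             (mu % (1.0 + a * mu)));
      double p2 = x2 / ((double)N - (double)P);
      phi(g) = p2 > 1.0 ? p2 : 1.0;
    }
  }

  return List::create(_["estimate"] = est, _["se"] = se, _["alpha"] = alpha,
                      _["phi"] = phi, _["status"] = status,
                      _["iterations"] = iters);
}
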