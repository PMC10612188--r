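// Weibull accelerated failure time model: Newton-Raphson maximum likelihood
// on (beta, log sigma) with analytic gradient and Hessian, plus a warm-started
// profile-likelihood sweep over hinge breakpoints for threshold regression.
//
// Model: log T = X beta + sigma W, W ~ standard Gumbel (minimum).
// Per-observation log likelihood (y = log t, s = log sigma, z = (y - X beta)/sigma):
//   event:    -s - y + z - exp(z)
//   censored: -exp(z)

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double aft_loglik(const mat& X, const vec& y, const vec& d,
                         const vec& beta, double s) {
  const double sigma = std::exp(s);
  vec z = (y - X * beta) / sigma;
  if (z.max() > 650.0) return -datum::inf;  // exp would overflow
  vec ez = exp(z);
  double ll = accu(d % (z - y)) - s * accu(d) - accu(ez);
  return std::isfinite(ll) ? ll : -datum::inf;
}

// gradient and Hessian over theta = (beta, s)
static void aft_derivs(const mat& X, const vec& y, const vec& d,
                       const vec& beta, double s,
                       vec& grad, mat& hess) {
  const double sigma = std::exp(s);
  const uword p = X.n_cols;
  vec z = (y - X * beta) / sigma;
  vec ez = exp(clamp(z, -700.0, 650.0));

  // gradient
  vec w = (ez - d) / sigma;                       // d ll / d eta_i, summed via X
  grad.set_size(p + 1);
  grad.head(p) = X.t() * w;
  grad(p) = accu(z % ez - d % (1.0 + z));

  // Hessian
  vec a = -ez / (sigma * sigma);                  // d2 ll / d eta^2
  vec b = -(z % ez + ez - d) / sigma;             // d2 ll / d eta d s
  double hss = accu(-z % ez % (1.0 + z) + d % z); // d2 ll / d s^2
  hess.set_size(p + 1, p + 1);
  hess.submat(0, 0, p - 1, p - 1) = X.t() * (X.each_col() % a);
  vec hbs = X.t() * b;
  hess.submat(0, p, p - 1, p) = hbs;
  hess.submat(p, 0, p, p - 1) = hbs.t();
  hess(p, p) = hss;
}

struct AftSolution {
  vec beta;
  double s;
  double loglik;
  vec grad;
  mat hess;
  int iter;
  bool converged;
};

// Newton with ridge damping and step halving; tol on max |gradient|.
static AftSolution aft_newton(const mat& X, const vec& y, const vec& d,
                              vec beta, double s,
                              int maxit, double tol) {
  const uword p = X.n_cols;
  AftSolution out;
  double ll = aft_loglik(X, y, d, beta, s);
  if (!std::isfinite(ll)) {  // fall back to a crude but safe start
    beta.zeros();
    beta(0) = median(y);
    s = 0.0;
    ll = aft_loglik(X, y, d, beta, s);
  }
  vec grad;
  mat hess;
  bool converged = false;
  int iter = 0;
  // gradient tolerance scales with |loglik| (itself O(n)), mirroring the
  // relative criteria of standard survival fitters
  for (; iter < maxit; ++iter) {
    aft_derivs(X, y, d, beta, s, grad, hess);
    if (norm(grad, "inf") < tol * (1.0 + std::fabs(ll))) {
      converged = true; break;
    }
    vec step;
    double ridge = 0.0;
    bool solved = false;
    for (int r = 0; r < 8 && !solved; ++r) {
      mat H = -hess;
      if (ridge > 0.0) H.diag() += ridge;
      solved = solve(step, H, grad, solve_opts::no_approx);
      if (solved && !step.is_finite()) solved = false;
      ridge = (ridge == 0.0) ? 1e-6 : ridge * 100.0;
    }
    if (!solved) break;
    // step halving to guarantee ascent
    double t = 1.0;
    bool improved = false;
    for (int h = 0; h < 40; ++h) {
      vec beta_new = beta + t * step.head(p);
      double s_new = s + t * step(p);
      double ll_new = aft_loglik(X, y, d, beta_new, s_new);
      if (std::isfinite(ll_new) && ll_new >= ll - 1e-12) {
        beta = beta_new; s = s_new;
        improved = (ll_new > ll + 1e-12) || norm(t * step, "inf") < 1e-10;
        ll = ll_new;
        break;
      }
      t *= 0.5;
    }
    if (!improved &&
        norm(grad, "inf") < 1e-5 * (1.0 + std::fabs(ll))) {
      converged = true; break;
    }
    if (!improved) break;
  }
  aft_derivs(X, y, d, beta, s, grad, hess);
  if (norm(grad, "inf") < std::max(tol, 1e-7) * (1.0 + std::fabs(ll)))
    converged = true;
  out.beta = beta;
  out.s = s;
  out.loglik = ll;
  out.grad = grad;
  out.hess = hess;
  out.iter = iter;
  out.converged = converged;
  return out;
}

// [[Rcpp::export]]
Rcpp::List aft_newton_cpp(const arma::mat& X, const arma::vec& y,
                          const arma::vec& d, const arma::vec& beta0,
                          double s0, int maxit = 100, double tol = 1e-9) {
  AftSolution sol = aft_newton(X, y, d, beta0, s0, maxit, tol);
  return Rcpp::List::create(
    Rcpp::Named("beta") = sol.beta,
    Rcpp::Named("log_sigma") = sol.s,
    Rcpp::Named("loglik") = sol.loglik,
    Rcpp::Named("grad") = sol.grad,
    Rcpp::Named("hess") = sol.hess,
    Rcpp::Named("iter") = sol.iter,
    Rcpp::Named("converged") = sol.converged);
}

// [[Rcpp::export]]
double aft_loglik_cpp(const arma::mat& X, const arma::vec& y,
                      const arma::vec& d, const arma::vec& beta, double s) {
  return aft_loglik(X, y, d, beta, s);
}

// Profile of the two-piecewise model over candidate breakpoints.
// X0: covariate block including intercept; x: exposure.
// At each k the design is [X0, pmin(x,k), pmax(x-k,0)]; fits are warm-started
// from the previous breakpoint's solution.
// [[Rcpp::export]]
Rcpp::List aft_profile_cpp(const arma::mat& X0, const arma::vec& x,
                           const arma::vec& y, const arma::vec& d,
                           const arma::vec& grid, const arma::vec& beta0,
                           double s0, int maxit = 100, double tol = 1e-8) {
  const uword n = X0.n_rows, p0 = X0.n_cols, m = grid.n_elem;
  mat X(n, p0 + 2);
  X.cols(0, p0 - 1) = X0;
  vec loglik(m), b_below(m), b_above(m), sig(m);
  ivec conv(m);
  vec beta = beta0;  // length p0 + 2
  double s = s0;
  for (uword j = 0; j < m; ++j) {
    const double k = grid(j);
    X.col(p0) = min(x, k * ones(n));
    X.col(p0 + 1) = max(x - k, zeros(n));
    AftSolution sol = aft_newton(X, y, d, beta, s, maxit, tol);
    loglik(j) = sol.loglik;
    b_below(j) = sol.beta(p0);
    b_above(j) = sol.beta(p0 + 1);
    sig(j) = std::exp(sol.s);
    conv(j) = sol.converged ? 1 : 0;
    if (sol.converged) { beta = sol.beta; s = sol.s; }
  }
  return Rcpp::List::create(
    Rcpp::Named("loglik") = loglik,
    Rcpp::Named("beta_below") = b_below,
    Rcpp::Named("beta_above") = b_above,
    Rcpp::Named("sigma") = sig,
    Rcpp::Named("converged") = conv);
}
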