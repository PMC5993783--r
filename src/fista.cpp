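// Proximal-gradient (FISTA) inner loop for the elastic-net logistic
// discriminant. Mirrors the package's optimizer contract: backtracking line
// search on the smooth majorization, monotone safeguard (an accelerated step
// that would increase the objective is replaced by a plain descent step with
// momentum restart), convergence on relative objective change.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static double nll_mean(const vec& eta, const vec& y) {
  double s = 0.0;
  for (uword i = 0; i < eta.n_elem; ++i) {
    double e = eta[i];
    s += (e > 0 ? e : 0.0) + std::log1p(std::exp(-std::fabs(e))) - y[i] * e;
  }
  return s / eta.n_elem;
}

static double smooth_f(const vec& theta, const vec& eta, const vec& y,
                       const uvec& pen, double lam2) {
  double r = 0.0;
  for (uword j = 0; j < pen.n_elem; ++j) r += theta[pen[j]] * theta[pen[j]];
  return nll_mean(eta, y) + 0.5 * lam2 * r;
}

static vec smooth_g(const mat& Z, const vec& theta, const vec& eta,
                    const vec& y, const uvec& pen, double lam2) {
  vec p = 1.0 / (1.0 + exp(-eta));
  vec g = Z.t() * (p - y) / (double)Z.n_rows;
  for (uword j = 0; j < pen.n_elem; ++j) g[pen[j]] += lam2 * theta[pen[j]];
  return g;
}

static double pen_l1(const vec& theta, const uvec& pen, double lam1) {
  double s = 0.0;
  for (uword j = 0; j < pen.n_elem; ++j) s += std::fabs(theta[pen[j]]);
  return lam1 * s;
}

static vec prox(vec theta, const uvec& pen, double t) {
  for (uword j = 0; j < pen.n_elem; ++j) {
    double v = theta[pen[j]];
    double a = std::fabs(v) - t;
    theta[pen[j]] = a > 0 ? (v > 0 ? a : -a) : 0.0;
  }
  return theta;
}

// [[Rcpp::export]]
Rcpp::List fista_enet_cpp(const arma::mat& Z, const arma::vec& y,
                          const arma::uvec& pen, double lam1, double lam2,
                          arma::vec theta, double tol, int max_iter,
                          double step0) {
  vec x = theta, xp = theta;
  vec Zx = Z * x, Zxp = Zx;
  double t_mom = 1.0, step = step0;
  double f_x = smooth_f(x, Zx, y, pen, lam2) + pen_l1(x, pen, lam1);
  std::vector<double> trace;
  trace.reserve(max_iter + 1);
  trace.push_back(f_x);
  bool converged = false;
  int it = 0;
  while (it < max_iter) {
    ++it;
    double cmom = (t_mom - 1.0) / (t_mom + 1.0);
    vec v = x + cmom * (x - xp);
    vec Zv = Zx + cmom * (Zx - Zxp);
    double fv = smooth_f(v, Zv, y, pen, lam2);
    vec gv = smooth_g(Z, v, Zv, y, pen, lam2);
    vec cand, Zcand, d;
    for (;;) {
      cand = prox(v - step * gv, pen, step * lam1);
      Zcand = Z * cand;
      d = cand - v;
      if (smooth_f(cand, Zcand, y, pen, lam2) <=
          fv + dot(gv, d) + dot(d, d) / (2.0 * step) + 1e-12)
        break;
      step /= 2.0;
    }
    double f_cand = smooth_f(cand, Zcand, y, pen, lam2) +
      pen_l1(cand, pen, lam1);
    if (f_cand > f_x) {
      double fx_s = smooth_f(x, Zx, y, pen, lam2);
      vec gx = smooth_g(Z, x, Zx, y, pen, lam2);
      for (;;) {
        cand = prox(x - step * gx, pen, step * lam1);
        Zcand = Z * cand;
        d = cand - x;
        if (smooth_f(cand, Zcand, y, pen, lam2) <=
            fx_s + dot(gx, d) + dot(d, d) / (2.0 * step) + 1e-12)
          break;
        step /= 2.0;
      }
      f_cand = smooth_f(cand, Zcand, y, pen, lam2) + pen_l1(cand, pen, lam1);
      t_mom = 1.0;
    } else {
      t_mom = (1.0 + std::sqrt(1.0 + 4.0 * t_mom * t_mom)) / 2.0;
    }
    xp = x; x = cand;
    Zxp = Zx; Zx = Zcand;
    double delta = f_x - f_cand;
    f_x = std::min(f_x, f_cand);
    trace.push_back(f_x);
    if (std::fabs(delta) < tol * (1.0 + std::fabs(f_x))) {
      converged = true;
      break;
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("theta") = x,
    Rcpp::Named("objective") = f_x,
    Rcpp::Named("trace") = trace,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("n_iter") = it,
    Rcpp::Named("step") = step);
}
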