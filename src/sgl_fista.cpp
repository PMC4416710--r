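// Monotone FISTA core for sparse-group LASSO logistic regression.
// Minimizes f(w) + lambda_s ||w_P||_1 + lambda_g sum_g gw_g ||w_g||_2 where
// f is the negative mean log likelihood of the +/-1 logistic model and P is
// the set of penalized coordinates (all but an optional unpenalized
// intercept column appended last).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double log1pexp_scalar(double x) {
  if (x <= 18.0) return std::log1p(std::exp(x));
  if (x <= 33.3) return x + std::exp(-x);
  return x;
}

static double negmll(const mat& X, const vec& y, const vec& w) {
  vec m = y % (X * w);
  double s = 0.0;
  for (uword i = 0; i < m.n_elem; ++i) s += log1pexp_scalar(-m[i]);
  return s / m.n_elem;
}

static vec grad_negmll(const mat& X, const vec& y, const vec& w) {
  vec m = y % (X * w);
  vec sig(m.n_elem);
  for (uword i = 0; i < m.n_elem; ++i) sig[i] = 1.0 / (1.0 + std::exp(m[i]));
  return -(X.t() * (y % sig)) / (double)X.n_rows;
}

// prox of t * (lambda_s ||.||_1 + lambda_g sum_g gw_g ||.||_2) on the first
// d_pen coordinates; groups is 0-based of length d_pen with values < G.
static vec prox_sgl_cpp(const vec& v, double t, double ls, double lg,
                        const ivec& groups, const vec& gw, uword d_pen,
                        uword G) {
  vec u = v;
  double thr = t * ls;
  if (thr > 0) {
    for (uword j = 0; j < d_pen; ++j) {
      double a = std::abs(v[j]) - thr;
      u[j] = a > 0 ? (v[j] > 0 ? a : -a) : 0.0;
    }
  }
  if (lg > 0) {
    vec gn(G, fill::zeros);
    for (uword j = 0; j < d_pen; ++j) gn[groups[j]] += u[j] * u[j];
    gn = sqrt(gn);
    vec scale(G);
    for (uword g = 0; g < G; ++g) {
      double lam = t * lg * gw[g];
      scale[g] = gn[g] > lam ? 1.0 - lam / gn[g] : 0.0;
    }
    for (uword j = 0; j < d_pen; ++j) u[j] *= scale[groups[j]];
  }
  return u;
}

static double penalty_val(const vec& w, double ls, double lg,
                          const ivec& groups, const vec& gw, uword d_pen,
                          uword G) {
  double p = 0.0;
  if (ls > 0) for (uword j = 0; j < d_pen; ++j) p += ls * std::abs(w[j]);
  if (lg > 0) {
    vec gn(G, fill::zeros);
    for (uword j = 0; j < d_pen; ++j) gn[groups[j]] += w[j] * w[j];
    for (uword g = 0; g < G; ++g) p += lg * gw[g] * std::sqrt(gn[g]);
  }
  return p;
}

// [[Rcpp::export]]
Rcpp::List sgl_fista_cpp(const arma::mat& X, const arma::vec& y,
                         const arma::ivec& groups, double lambda_s,
                         double lambda_g, const arma::vec& gw,
                         const arma::vec& w0, int max_iter, double tol,
                         double L, int d_pen) {
  uword dd = X.n_cols;
  uword G = gw.n_elem;
  double t = L > 0 ? 1.0 / L : 1.0;
  vec w = w0, v = w0;
  double theta = 1.0;
  double J_w = negmll(X, y, w) +
    penalty_val(w, lambda_s, lambda_g, groups, gw, (uword)d_pen, G);
  std::vector<double> trace;
  trace.push_back(J_w);
  bool converged = false;
  int it = 0;

  auto bt_step = [&](const vec& z0, double t0, vec& z1) -> double {
    double fz = negmll(X, y, z0);
    vec gz = grad_negmll(X, y, z0);
    double tt = t0;
    for (;;) {
      z1 = prox_sgl_cpp(z0 - tt * gz, tt, lambda_s, lambda_g, groups, gw,
                        (uword)d_pen, G);
      vec dz = z1 - z0;
      double rhs = fz + dot(gz, dz) + dot(dz, dz) / (2.0 * tt) + 1e-14;
      if (negmll(X, y, z1) <= rhs || tt < 1e-18) break;
      tt *= 0.5;
    }
    return tt;
  };

  vec w_new(dd);
  while (it < max_iter) {
    ++it;
    t = bt_step(v, t, w_new);
    double J_new = negmll(X, y, w_new) +
      penalty_val(w_new, lambda_s, lambda_g, groups, gw, (uword)d_pen, G);
    if (J_new > J_w + 1e-14) {
      // monotone safeguard: plain proximal step from w, restart momentum
      t = bt_step(w, t, w_new);
      J_new = negmll(X, y, w_new) +
        penalty_val(w_new, lambda_s, lambda_g, groups, gw, (uword)d_pen, G);
      theta = 1.0;
      v = w_new;
    } else {
      double theta_new = (1.0 + std::sqrt(1.0 + 4.0 * theta * theta)) / 2.0;
      v = w_new + ((theta - 1.0) / theta_new) * (w_new - w);
      theta = theta_new;
    }
    if (J_new > J_w) J_new = J_w;  // guard the trace against roundoff
    trace.push_back(J_new);
    double dw = norm(w_new - w, 2) / std::max(1.0, norm(w, 2));
    double dJ = (J_w - J_new) / std::max(1.0, std::abs(J_w));
    w = w_new;
    J_w = J_new;
    if (dJ < tol && dw < tol) { converged = true; break; }
  }
  return Rcpp::List::create(
    Rcpp::Named("w") = w, Rcpp::Named("objective") = J_w,
    Rcpp::Named("n_iter") = it, Rcpp::Named("converged") = converged,
    Rcpp::Named("trace") = trace);
}
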