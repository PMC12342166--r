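// Entropic OT kernels: balanced Sinkhorn, unbalanced (robust) Sinkhorn-Knopp,
// and Dykstra/Bregman projections for entropic partial OT.
//
// All iterations run in the log domain when the Gibbs kernel exp(-C/eta)
// would underflow; the balanced/unbalanced solvers first try plain diagonal
// scaling (fast BLAS path) and fall back to the log domain on non-finite
// scalings. Mass vectors passed here are strictly positive; zero-mass
// rows/columns are stripped and reinserted by the R wrappers.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// log-sum-exp over each row, robust to all -Inf rows
static vec row_lse(const mat& L) {
  vec mx = max(L, 1);
  vec out(L.n_rows);
  for (uword i = 0; i < L.n_rows; ++i) {
    if (!std::isfinite(mx(i))) { out(i) = mx(i); continue; }
    double s = 0.0;
    for (uword j = 0; j < L.n_cols; ++j) s += std::exp(L(i, j) - mx(i));
    out(i) = mx(i) + std::log(s);
  }
  return out;
}

static vec col_lse(const mat& L) { return row_lse(L.t()); }

static double full_lse(const mat& L) {
  double mx = L.max();
  if (!std::isfinite(mx)) return mx;
  return mx + std::log(accu(exp(L - mx)));
}

static mat plan_from_potentials(const mat& C, const vec& f, const vec& g,
                                double eta) {
  mat logT = -C / eta;
  logT.each_col() += f / eta;
  logT.each_row() += (g / eta).t();
  return exp(logT);
}

// annealing schedule for small regularization (epsilon-scaling): start at a
// moderate eta and sharpen geometrically, warm-starting each stage, so the
// iterate tracks the regularization path instead of stalling in a wrong
// active-set basin
static std::vector<double> eta_schedule(double eta) {
  std::vector<double> etas;
  const double eta0 = 0.1;
  if (eta < eta0) {
    for (double e = eta0; e > eta * 1.5; e /= 3.0) etas.push_back(e);
  }
  etas.push_back(eta);
  return etas;
}

// ---- balanced Sinkhorn ----------------------------------------------------

static Rcpp::List sinkhorn_log(const mat& C, const vec& a, const vec& b,
                               double eta, double tol, int max_iter) {
  const vec loga = log(a), logb = log(b);
  vec f(a.n_elem, fill::zeros), g(b.n_elem, fill::zeros);
  const std::vector<double> etas = eta_schedule(eta);
  bool converged = false;
  int total_it = 0;
  for (size_t k = 0; k < etas.size(); ++k) {
    const double e = etas[k];
    const bool last = (k + 1 == etas.size());
    const double tol_k = last ? tol : std::max(tol, 1e-6);
    const int cap = last ? max_iter : std::min(max_iter, 2000);
    const mat A = -C / e;
    converged = false;
    int it = 0;
    while (it < cap) {
      ++it;
      f = e * (loga - row_lse(A + repmat((g / e).t(), a.n_elem, 1)));
      g = e * (logb - col_lse(A.each_col() + f / e));
      if (it % 10 == 0 || it == cap) {
        mat T = plan_from_potentials(C, f, g, e);
        double err = norm(sum(T, 1) - a, 1);  // column marginals exact here
        if (err <= tol_k) { converged = true; break; }
      }
    }
    total_it += it;
  }
  mat T = plan_from_potentials(C, f, g, eta);
  return Rcpp::List::create(Rcpp::Named("plan") = T,
                            Rcpp::Named("iterations") = total_it,
                            Rcpp::Named("converged") = converged);
}

// [[Rcpp::export]]
Rcpp::List ot_sinkhorn_cpp(const arma::mat& C, const arma::vec& a,
                           const arma::vec& b, double eta, double tol,
                           int max_iter) {
  // plain scaling path when the kernel cannot underflow badly
  if (C.max() / eta < 500.0) {
    mat K = exp(-C / eta);
    vec u(a.n_elem, fill::ones), v(b.n_elem, fill::ones);
    bool converged = false, bad = false;
    int it = 0;
    while (it < max_iter) {
      ++it;
      u = a / (K * v);
      v = b / (K.t() * u);
      if (it % 10 == 0 || it == max_iter) {
        if (!u.is_finite() || !v.is_finite()) { bad = true; break; }
        mat T = diagmat(u) * K * diagmat(v);
        if (norm(sum(T, 1) - a, 1) <= tol) { converged = true; break; }
      }
    }
    if (!bad) {
      mat T = diagmat(u) * K * diagmat(v);
      return Rcpp::List::create(Rcpp::Named("plan") = T,
                                Rcpp::Named("iterations") = it,
                                Rcpp::Named("converged") = converged);
    }
  }
  return sinkhorn_log(C, a, b, eta, tol, max_iter);
}

// ---- unbalanced (robust) Sinkhorn-Knopp -----------------------------------

static Rcpp::List usinkhorn_log(const mat& C, const vec& a, const vec& b,
                                double eta, double eps, double tol,
                                int max_iter) {
  const double fi = eps / (eps + eta);
  const vec loga = log(a), logb = log(b);
  vec f(a.n_elem, fill::zeros), g(b.n_elem, fill::zeros);
  const mat A = -C / eta;
  vec ra_prev(a.n_elem, fill::zeros), cb_prev(b.n_elem, fill::zeros);
  bool converged = false;
  int it = 0;
  while (it < max_iter) {
    ++it;
    f = fi * eta * (loga - row_lse(A + repmat((g / eta).t(), a.n_elem, 1)));
    g = fi * eta * (logb - col_lse(A.each_col() + f / eta));
    if (it % 10 == 0 || it == max_iter) {
      mat T = plan_from_potentials(C, f, g, eta);
      vec ra = sum(T, 1), cb = sum(T, 0).t();
      double err = norm(ra - ra_prev, 1) + norm(cb - cb_prev, 1);
      if (err <= tol) { converged = true; break; }
      ra_prev = ra; cb_prev = cb;
    }
  }
  mat T = plan_from_potentials(C, f, g, eta);
  return Rcpp::List::create(Rcpp::Named("plan") = T,
                            Rcpp::Named("iterations") = it,
                            Rcpp::Named("converged") = converged);
}

// [[Rcpp::export]]
Rcpp::List ot_usinkhorn_cpp(const arma::mat& C, const arma::vec& a,
                            const arma::vec& b, double eta, double eps,
                            double tol, int max_iter) {
  if (C.max() / eta < 500.0) {
    const double fi = eps / (eps + eta);
    mat K = exp(-C / eta);
    vec u(a.n_elem, fill::ones), v(b.n_elem, fill::ones);
    vec ra_prev(a.n_elem, fill::zeros), cb_prev(b.n_elem, fill::zeros);
    bool converged = false, bad = false;
    int it = 0;
    while (it < max_iter) {
      ++it;
      u = pow(a / (K * v), fi);
      v = pow(b / (K.t() * u), fi);
      if (it % 10 == 0 || it == max_iter) {
        if (!u.is_finite() || !v.is_finite()) { bad = true; break; }
        mat T = diagmat(u) * K * diagmat(v);
        vec ra = sum(T, 1), cb = sum(T, 0).t();
        double err = norm(ra - ra_prev, 1) + norm(cb - cb_prev, 1);
        if (err <= tol) { converged = true; break; }
        ra_prev = ra; cb_prev = cb;
      }
    }
    if (!bad) {
      mat T = diagmat(u) * K * diagmat(v);
      return Rcpp::List::create(Rcpp::Named("plan") = T,
                                Rcpp::Named("iterations") = it,
                                Rcpp::Named("converged") = converged);
    }
  }
  return usinkhorn_log(C, a, b, eta, eps, tol, max_iter);
}

// ---- entropic partial OT via Dykstra projections --------------------------
//
// KL-Bregman projections onto { T1 <= a }, { T'1 <= b } and { 1'T1 = s },
// each a diagonal (or global) rescaling, with Dykstra correction terms; the
// corrections stay rank-structured (row vector, column vector, scalar).

static int partial_dykstra_stage(mat& lK, vec& lq1, vec& lq2, double& lq3,
                                 const vec& a, const vec& b,
                                 const vec& loga, const vec& logb,
                                 double logs, double s, double tol,
                                 int max_iter, bool& converged) {
  const uword n = a.n_elem, m = b.n_elem;
  mat T_prev = exp(lK);
  converged = false;
  int it = 0;
  while (it < max_iter) {
    ++it;
    // rows: T1 <= a   (Dykstra: q_new = x_prev / P(x_prev * q_old))
    lK.each_col() += lq1;
    vec d1 = min(loga - row_lse(lK), zeros<vec>(n));
    lK.each_col() += d1;
    lq1 = -d1;
    // columns: T'1 <= b
    lK.each_row() += lq2.t();
    vec d2 = min(logb - col_lse(lK), zeros<vec>(m));
    lK.each_row() += d2.t();
    lq2 = -d2;
    // total mass: 1'T1 = s
    lK += lq3;
    double d3 = logs - full_lse(lK);
    lK += d3;
    lq3 = -d3;
    // converged when the iterate is simultaneously stationary (plan change)
    // and feasible for all three constraint sets; plan change alone can go
    // quiet while mass is still being redistributed between cells
    if (it % 10 == 0 || it == max_iter) {
      mat T = exp(lK);
      if (!T.is_finite()) break;
      double err = accu(abs(T - T_prev)) +
        accu(clamp(sum(T, 1) - a, 0.0, datum::inf)) +
        accu(clamp(sum(T, 0).t() - b, 0.0, datum::inf)) +
        std::fabs(accu(T) - s);
      // L1 quantities scale with the transported mass, so the tolerance is
      // mass-relative (a no-op for unit-mass problems)
      if (err <= tol * std::max(1.0, s)) { converged = true; break; }
      T_prev = T;
    }
  }
  return it;
}

// [[Rcpp::export]]
Rcpp::List ot_partial_dykstra_cpp(const arma::mat& C, const arma::vec& a,
                                  const arma::vec& b, double eta, double s,
                                  double tol, int max_iter) {
  const uword n = a.n_elem, m = b.n_elem;
  const vec loga = log(a), logb = log(b);
  const double logs = std::log(s);
  const std::vector<double> etas = eta_schedule(eta);
  mat lK = -C / etas[0];
  lK += logs - full_lse(lK);  // start on the total-mass constraint set
  vec lq1(n, fill::zeros), lq2(m, fill::zeros);
  double lq3 = 0.0;
  bool converged = false;
  int total_it = 0;
  for (size_t k = 0; k < etas.size(); ++k) {
    if (k > 0) {
      // warm start across the annealing schedule: the converged stage
      // solution has the form log T = -C/e_old - A_i - B_j + G, so the
      // row/column log-multipliers A, B are recovered from row/column means,
      // rescaled to the new eta (duals alpha = e*A are continuous along the
      // regularization path), pre-applied to the new kernel, and mirrored in
      // the Dykstra corrections so the state is self-consistent
      const double scale = etas[k - 1] / etas[k];
      mat M = lK + C / etas[k - 1];
      const double g = accu(M) / (n * m);
      // gauge: slack constraints carry zero multiplier, so shift each
      // multiplier vector to put its minimum (the slack rows/columns) at 0
      vec A = -(sum(M, 1) / m - g);
      vec B = -(sum(M, 0).t() / n - g);
      A = clamp(A - A.min(), 0.0, datum::inf) * scale;
      B = clamp(B - B.min(), 0.0, datum::inf) * scale;
      lK = -C / etas[k];
      lK.each_col() -= A;
      lK.each_row() -= B.t();
      lK += logs - full_lse(lK);
      lq1 = A;
      lq2 = B;
      lq3 = 0.0;
    }
    const bool last = (k + 1 == etas.size());
    total_it += partial_dykstra_stage(
        lK, lq1, lq2, lq3, a, b, loga, logb, logs, s,
        last ? tol : std::max(tol, 1e-8),
        last ? max_iter : std::min(max_iter, 2000), converged);
  }
  mat T = exp(lK);
  return Rcpp::List::create(Rcpp::Named("plan") = T,
                            Rcpp::Named("iterations") = total_it,
                            Rcpp::Named("converged") = converged);
}
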