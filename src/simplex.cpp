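// Bounded-variable two-phase primal simplex for the LPs behind FBA/FVA.
//
//     optimise  c'x   subject to   A x = b,   l <= x <= u
//
// Dense; sized for networks of a few hundred reactions. Phase 1 drives
// signed artificial columns to zero, phase 2 optimises the true objective.
// Dantzig pricing with a permanent switch to Bland's rule when the
// objective stalls (anti-cycling). The basis inverse is refactorised
// periodically and the final basic solution is recomputed from scratch so
// the steady-state residual of returned solutions is at rounding level.

#include <RcppArmadillo.h>
using namespace arma;

static const double DJ_TOL = 1e-9;     // reduced-cost tolerance
static const double PIV_TOL = 1e-8;    // minimum pivot magnitude
static const double FEAS_TOL = 1e-7;   // phase-1 infeasibility tolerance
static const double BND_TOL = 1e-9;    // ratio-test bound slack

namespace {

struct SimplexState {
  const mat& A;          // m x n structural columns
  vec b;
  vec l, u;              // length N = n + m (structurals + artificials)
  ivec asign;            // artificial column signs (+1/-1)
  int m, n, N;
  ivec basis;            // m basic variable indices
  ivec stat;             // 0 at lower, 1 at upper, 2 basic, 3 free at zero
  vec xval;              // nonbasic values (basic entries refreshed on demand)
  mat Binv;
  int iter_total = 0;

  SimplexState(const mat& A_, const vec& b_) : A(A_), b(b_) {
    m = A.n_rows; n = A.n_cols; N = n + m;
  }

  // column j of the working matrix (structural or artificial)
  vec colvec_of(int j) const {
    if (j < n) return A.col(j);
    vec e(m, fill::zeros);
    e(j - n) = (double)asign(j - n);
    return e;
  }

  void refactor() {
    mat B(m, m);
    for (int k = 0; k < m; ++k) B.col(k) = colvec_of(basis(k));
    mat I = eye(m, m);
    bool ok = solve(Binv, B, I, solve_opts::no_approx);
    if (!ok) Rcpp::stop("simplex: singular basis during refactorisation");
  }

  vec nonbasic_contrib() const {
    vec ax(m, fill::zeros);
    for (int j = 0; j < N; ++j) {
      if (stat(j) == 2) continue;
      double v = xval(j);
      if (v != 0.0) {
        if (j < n) ax += A.col(j) * v;
        else ax(j - n) += asign(j - n) * v;
      }
    }
    return ax;
  }

  void recompute_basics() {
    vec rhs = b - nonbasic_contrib();
    vec xb = Binv * rhs;
    for (int k = 0; k < m; ++k) xval(basis(k)) = xb(k);
  }

  // exact refresh via a fresh factorisation (used on exit)
  void polish() {
    mat B(m, m);
    for (int k = 0; k < m; ++k) B.col(k) = colvec_of(basis(k));
    vec rhs = b - nonbasic_contrib();
    vec xb;
    if (solve(xb, B, rhs, solve_opts::no_approx)) {
      for (int k = 0; k < m; ++k) xval(basis(k)) = xb(k);
    } else {
      recompute_basics();
    }
  }

  // core loop; returns 0 optimal, 2 unbounded, 3 iteration trouble
  int optimise(const vec& cost, int max_iter) {
    bool bland = false;
    int stall = 0;
    double last_obj = -datum::inf;
    int since_refactor = 0;

    for (int it = 0; it < max_iter; ++it, ++iter_total) {
      if (since_refactor >= 64) { refactor(); recompute_basics(); since_refactor = 0; }

      // duals and reduced costs (structural part via one BLAS matvec)
      vec cb(m);
      for (int k = 0; k < m; ++k) cb(k) = cost(basis(k));
      vec y = Binv.t() * cb;
      vec ay = A.t() * y;

      int enter = -1, direction = 0;
      double best = 0.0;
      for (int j = 0; j < N; ++j) {
        int sj = stat(j);
        if (sj == 2) continue;
        if (u(j) - l(j) < 1e-12 && sj != 3) continue;  // fixed
        double aj_y = (j < n) ? ay(j) : y(j - n) * asign(j - n);
        double dj = cost(j) - aj_y;
        int dir = 0;
        if (sj == 0 && dj > DJ_TOL) dir = +1;
        else if (sj == 1 && dj < -DJ_TOL) dir = -1;
        else if (sj == 3 && std::abs(dj) > DJ_TOL) dir = (dj > 0) ? +1 : -1;
        if (dir == 0) continue;
        if (bland) { enter = j; direction = dir; break; }
        if (std::abs(dj) > best) { best = std::abs(dj); enter = j; direction = dir; }
      }
      if (enter < 0) return 0;  // optimal

      vec w = Binv * colvec_of(enter);

      // ratio test: x_enter moves by t*direction, basics move by -direction*w*t
      double t_own = datum::inf;
      if (direction > 0 && std::isfinite(u(enter))) t_own = u(enter) - xval(enter);
      if (direction < 0 && std::isfinite(l(enter))) t_own = xval(enter) - l(enter);

      double t_min = t_own;
      int leave = -1;       // index into basis
      int leave_to = 0;     // 0 -> lower, 1 -> upper
      double leave_g = 0.0;
      for (int k = 0; k < m; ++k) {
        double g = -direction * w(k);
        if (std::abs(g) <= PIV_TOL) continue;
        int bi = basis(k);
        double xb = xval(bi);
        double t;
        int to;
        if (g > 0) {
          if (!std::isfinite(u(bi))) continue;
          t = (u(bi) - xb + BND_TOL) / g; to = 1;
        } else {
          if (!std::isfinite(l(bi))) continue;
          t = (xb - l(bi) + BND_TOL) / (-g); to = 0;
        }
        if (t < 0) t = 0;
        if (t < t_min - 1e-12 ||
            (t < t_min + 1e-12 &&
             (leave < 0 ||
              (bland ? basis(k) < basis(leave)
                     : std::abs(g) > std::abs(leave_g))))) {
          if (t < t_min) t_min = t;
          leave = k; leave_to = to; leave_g = g;
        }
      }

      if (!std::isfinite(t_min)) return 2;  // unbounded

      if (leave < 0 || t_own <= t_min + 1e-12) {
        // bound flip (or hitting own bound first)
        if (!std::isfinite(t_own)) return 2;
        xval(enter) += direction * t_own;
        for (int k = 0; k < m; ++k) xval(basis(k)) -= direction * w(k) * t_own;
        stat(enter) = (direction > 0) ? 1 : 0;
        if (stat(enter) == 1 && !std::isfinite(u(enter))) stat(enter) = 0;
      } else {
        double t = t_min;
        xval(enter) += direction * t;
        for (int k = 0; k < m; ++k) xval(basis(k)) -= direction * w(k) * t;
        int out = basis(leave);
        // snap the leaving variable onto its bound
        xval(out) = (leave_to == 1) ? u(out) : l(out);
        stat(out) = leave_to;
        if (!std::isfinite(xval(out))) { xval(out) = 0; stat(out) = 3; }
        basis(leave) = enter;
        stat(enter) = 2;
        // eta update of Binv
        double piv = w(leave);
        rowvec prow = Binv.row(leave) / piv;
        for (int i = 0; i < m; ++i) {
          if (i == leave) continue;
          double wi = w(i);
          if (wi != 0.0) Binv.row(i) -= wi * prow;
        }
        Binv.row(leave) = prow;
        ++since_refactor;
      }

      // stall detection -> Bland
      double obj = 0.0;
      for (int j = 0; j < N; ++j) obj += cost(j) * xval(j);
      if (obj > last_obj + 1e-12) { last_obj = obj; stall = 0; }
      else if (++stall > 5 * (m + 20) && !bland) { bland = true; stall = 0; }
    }
    return 3;
  }
};

}  // namespace

// Batch min/max of single variables over {A x = b, l <= x <= u}, sharing one
// phase-1 solve and warm-starting every sub-problem from the previous basis
// (the feasible region is identical across sub-problems, so the incumbent
// basic solution stays feasible when only the objective changes).
// [[Rcpp::export(name = ".simplex_fva")]]
Rcpp::List simplex_fva(const arma::mat& A, const arma::vec& b,
                       const arma::ivec& js, const arma::vec& lb,
                       const arma::vec& ub, int max_iter = 50000) {
  const int m = A.n_rows, n = A.n_cols;
  if ((int)b.n_elem != m || (int)lb.n_elem != n || (int)ub.n_elem != n)
    Rcpp::stop("simplex_fva: dimension mismatch");
  for (int j = 0; j < n; ++j)
    if (lb(j) > ub(j) + 1e-12) Rcpp::stop("simplex_fva: lb > ub for variable %d", j + 1);

  SimplexState st(A, b);
  const int N = st.N;
  st.l.set_size(N); st.u.set_size(N);
  st.stat.set_size(N); st.xval.set_size(N);
  st.asign.set_size(m); st.basis.set_size(m);
  for (int j = 0; j < n; ++j) {
    st.l(j) = lb(j); st.u(j) = ub(j);
    if (std::isfinite(lb(j))) { st.stat(j) = 0; st.xval(j) = lb(j); }
    else if (std::isfinite(ub(j))) { st.stat(j) = 1; st.xval(j) = ub(j); }
    else { st.stat(j) = 3; st.xval(j) = 0.0; }
  }
  vec r = b;
  for (int j = 0; j < n; ++j)
    if (st.xval(j) != 0.0) r -= A.col(j) * st.xval(j);
  for (int i = 0; i < m; ++i) {
    st.asign(i) = (r(i) >= 0) ? 1 : -1;
    int aj = n + i;
    st.l(aj) = 0.0; st.u(aj) = datum::inf;
    st.basis(i) = aj; st.stat(aj) = 2;
    st.xval(aj) = std::abs(r(i));
  }
  st.refactor();
  st.recompute_basics();

  const int K = js.n_elem;
  Rcpp::NumericVector vmin(K), vmax(K);
  Rcpp::IntegerVector smin(K), smax(K);

  vec c1(N, fill::zeros);
  for (int i = 0; i < m; ++i) c1(n + i) = -1.0;
  int s1 = st.optimise(c1, max_iter);
  double infeas = 0.0;
  for (int i = 0; i < m; ++i) infeas += std::abs(st.xval(n + i));
  if (s1 == 3 || infeas > FEAS_TOL) {
    int code = (s1 == 3) ? 3 : 1;
    for (int k = 0; k < K; ++k) { smin[k] = code; smax[k] = code; }
    return Rcpp::List::create(Rcpp::Named("min") = vmin, Rcpp::Named("max") = vmax,
                              Rcpp::Named("min_status") = smin,
                              Rcpp::Named("max_status") = smax);
  }
  for (int i = 0; i < m; ++i) st.u(n + i) = 0.0;

  vec cw(N, fill::zeros);
  for (int k = 0; k < K; ++k) {
    int j = js(k) - 1;  // R is 1-based
    if (j < 0 || j >= n) Rcpp::stop("simplex_fva: variable index out of range");
    cw(j) = -1.0;  // minimise = maximise -x_j
    int s = st.optimise(cw, max_iter);
    st.polish();
    vmin[k] = st.xval(j); smin[k] = s;
    cw(j) = 1.0;
    s = st.optimise(cw, max_iter);
    st.polish();
    vmax[k] = st.xval(j); smax[k] = s;
    cw(j) = 0.0;
  }
  return Rcpp::List::create(Rcpp::Named("min") = vmin, Rcpp::Named("max") = vmax,
                            Rcpp::Named("min_status") = smin,
                            Rcpp::Named("max_status") = smax);
}

// [[Rcpp::export(name = ".simplex_solve")]]
Rcpp::List simplex_solve(const arma::mat& A, const arma::vec& b,
                         const arma::vec& c, const arma::vec& lb,
                         const arma::vec& ub, bool maximise,
                         int max_iter = 50000) {
  const int m = A.n_rows, n = A.n_cols;
  if ((int)b.n_elem != m || (int)c.n_elem != n ||
      (int)lb.n_elem != n || (int)ub.n_elem != n)
    Rcpp::stop("simplex: dimension mismatch");
  for (int j = 0; j < n; ++j)
    if (lb(j) > ub(j) + 1e-12) Rcpp::stop("simplex: lb > ub for variable %d", j + 1);

  auto finish = [&](int status, const vec& x) {
    double obj = dot(c, x);
    return Rcpp::List::create(
        Rcpp::Named("status") = status,
        Rcpp::Named("objective") = obj,
        Rcpp::Named("x") = Rcpp::NumericVector(x.begin(), x.end()));
  };

  // trivial case: no equality rows
  if (m == 0) {
    vec x(n, fill::zeros);
    for (int j = 0; j < n; ++j) {
      double cj = maximise ? c(j) : -c(j);
      if (cj > 0) {
        if (!std::isfinite(ub(j))) return finish(2, x);
        x(j) = ub(j);
      } else if (cj < 0) {
        if (!std::isfinite(lb(j))) return finish(2, x);
        x(j) = lb(j);
      } else {
        x(j) = std::isfinite(lb(j)) ? lb(j) : (std::isfinite(ub(j)) ? ub(j) : 0.0);
      }
    }
    return finish(0, x);
  }

  SimplexState st(A, b);
  const int N = st.N;
  st.l.set_size(N); st.u.set_size(N);
  st.stat.set_size(N); st.xval.set_size(N);
  st.asign.set_size(m);
  st.basis.set_size(m);

  for (int j = 0; j < n; ++j) {
    st.l(j) = lb(j); st.u(j) = ub(j);
    if (std::isfinite(lb(j))) { st.stat(j) = 0; st.xval(j) = lb(j); }
    else if (std::isfinite(ub(j))) { st.stat(j) = 1; st.xval(j) = ub(j); }
    else { st.stat(j) = 3; st.xval(j) = 0.0; }
  }

  vec r = b;
  for (int j = 0; j < n; ++j)
    if (st.xval(j) != 0.0) r -= A.col(j) * st.xval(j);
  for (int i = 0; i < m; ++i) {
    st.asign(i) = (r(i) >= 0) ? 1 : -1;
    int aj = n + i;
    st.l(aj) = 0.0; st.u(aj) = datum::inf;
    st.basis(i) = aj;
    st.stat(aj) = 2;
    st.xval(aj) = std::abs(r(i));
  }
  st.Binv = eye(m, m);
  st.refactor();
  st.recompute_basics();

  // phase 1: drive artificials out
  vec c1(N, fill::zeros);
  for (int i = 0; i < m; ++i) c1(n + i) = -1.0;
  int s1 = st.optimise(c1, max_iter);
  if (s1 == 3) return finish(3, vec(n, fill::zeros));
  double infeas = 0.0;
  for (int i = 0; i < m; ++i) infeas += std::abs(st.xval(n + i));
  if (infeas > FEAS_TOL) return finish(1, vec(n, fill::zeros));

  // phase 2: true objective with artificials pinned at zero
  for (int i = 0; i < m; ++i) { st.u(n + i) = 0.0; st.xval(n + i) = std::max(0.0, std::min(st.xval(n + i), 0.0)); }
  vec c2(N, fill::zeros);
  for (int j = 0; j < n; ++j) c2(j) = maximise ? c(j) : -c(j);
  int s2 = st.optimise(c2, max_iter);

  st.polish();
  vec x(n);
  for (int j = 0; j < n; ++j) x(j) = st.xval(j);

  if (s2 == 2) return finish(2, x);
  if (s2 == 3) return finish(3, x);
  return finish(0, x);
}
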