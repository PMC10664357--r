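// Bounded-variable two-phase primal simplex for the FBA linear programs
//   maximize c'x  subject to  A x = b,  lb <= x <= ub
// Dense revised simplex; basis systems are re-solved each iteration, which is
// cheap at the problem sizes FBA inner problems reach here (tens to a few
// hundred rows). Dantzig pricing with a Bland fallback guards against cycling.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

const double PIV_TOL  = 1e-9;   // reduced-cost / pivot threshold
const double FEAS_TOL = 1e-7;   // phase-1 residual considered feasible

enum VStat { AT_LB = 0, AT_UB = 1, NB_FREE = 2, BASIC = 3 };

struct SimplexResult {
  int status;        // 0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit
  double objective;
  vec x;
};

// One simplex phase on the working problem (n structural + m artificial
// columns). Maximizes cc over the current basis/status; mutates everything in
// place. Returns 0 optimal, 2 unbounded, 3 iteration limit.
int run_phase(const mat& A, const vec& cc, const vec& lb, const vec& ub,
              uvec& basis, ivec& vstat, vec& x, int maxit) {
  const uword m = A.n_rows, N = A.n_cols;
  int iter = 0;
  const int bland_after = 200 + 40 * (int)(m + N);

  while (iter++ < maxit) {
    bool bland = iter > bland_after;
    mat B = A.cols(basis);
    vec cB(m);
    for (uword i = 0; i < m; ++i) cB(i) = cc(basis(i));
    vec y;
    if (!solve(y, B.t(), cB)) return 3;  // singular basis: give up

    // pricing
    sword enter = -1;
    int enter_dir = 0;  // +1 increase, -1 decrease
    double best = PIV_TOL;
    for (uword j = 0; j < N; ++j) {
      if (vstat(j) == BASIC) continue;
      double dj = cc(j) - dot(y, A.col(j));
      double viol = 0; int dir = 0;
      if (vstat(j) == AT_LB && dj > PIV_TOL) { viol = dj; dir = +1; }
      else if (vstat(j) == AT_UB && dj < -PIV_TOL) { viol = -dj; dir = -1; }
      else if (vstat(j) == NB_FREE && std::fabs(dj) > PIV_TOL) {
        viol = std::fabs(dj); dir = dj > 0 ? +1 : -1;
      }
      if (dir != 0) {
        if (bland) { enter = j; enter_dir = dir; break; }
        if (viol > best) { best = viol; enter = j; enter_dir = dir; }
      }
    }
    if (enter < 0) return 0;  // optimal

    vec w;
    if (!solve(w, B, (vec)A.col(enter))) return 3;

    // ratio test: x[enter] moves by s*t, basic i moves by -s*t*w(i)
    double s = (double)enter_dir;
    double tmax = datum::inf;
    sword leave = -1;        // row index in basis hitting its bound
    int leave_bound = 0;     // 0 -> lower, 1 -> upper
    bool flip = false;
    double span = ub(enter) - lb(enter);
    if (std::isfinite(span)) { tmax = span; flip = true; }
    double best_piv = 0;
    for (uword i = 0; i < m; ++i) {
      double delta = -s * w(i);
      uword bi = basis(i);
      double t_i = datum::inf; int bnd = 0;
      if (delta < -PIV_TOL) {
        if (std::isfinite(lb(bi))) t_i = (x(bi) - lb(bi)) / (-delta), bnd = 0;
      } else if (delta > PIV_TOL) {
        if (std::isfinite(ub(bi))) t_i = (ub(bi) - x(bi)) / delta, bnd = 1;
      } else continue;
      if (t_i < 0) t_i = 0;  // numerical guard
      if (t_i < tmax - PIV_TOL ||
          (t_i < tmax + PIV_TOL && leave >= 0 &&
           (bland ? basis(i) < basis(leave)
                  : std::fabs(w(i)) > best_piv))) {
        tmax = t_i; leave = i; leave_bound = bnd; flip = false;
        best_piv = std::fabs(w(i));
      }
    }
    if (!std::isfinite(tmax)) return 2;  // unbounded

    // apply step
    for (uword i = 0; i < m; ++i) x(basis(i)) += -s * tmax * w(i);
    x(enter) += s * tmax;
    if (flip && leave < 0) {
      vstat(enter) = (vstat(enter) == AT_LB) ? AT_UB : AT_LB;
      x(enter) = (vstat(enter) == AT_LB) ? lb(enter) : ub(enter);
    } else if (leave >= 0) {
      uword out = basis(leave);
      vstat(out) = leave_bound == 0 ? AT_LB : AT_UB;
      x(out) = leave_bound == 0 ? lb(out) : ub(out);
      basis(leave) = enter;
      vstat(enter) = BASIC;
    } else {
      return 2;  // no limit found
    }
  }
  return 3;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".simplex_cpp")]]
Rcpp::List simplex_cpp(const arma::mat& A, const arma::vec& b,
                       const arma::vec& cobj, const arma::vec& lb,
                       const arma::vec& ub, bool maximize, int maxit) {
  const uword m = A.n_rows, n = A.n_cols;
  vec c = maximize ? vec(cobj) : vec(-cobj);

  // working problem with m artificial columns
  mat Aw(m, n + m, fill::zeros);
  Aw.cols(0, n - 1) = A;
  vec lbw(n + m), ubw(n + m), x(n + m, fill::zeros);
  lbw.subvec(0, n - 1) = lb;  ubw.subvec(0, n - 1) = ub;
  lbw.subvec(n, n + m - 1).zeros();
  ubw.subvec(n, n + m - 1).fill(datum::inf);

  ivec vstat(n + m);
  for (uword j = 0; j < n; ++j) {
    if (std::isfinite(lb(j)))      { vstat(j) = AT_LB; x(j) = lb(j); }
    else if (std::isfinite(ub(j))) { vstat(j) = AT_UB; x(j) = ub(j); }
    else                           { vstat(j) = NB_FREE; x(j) = 0; }
  }
  vec r = b - Aw.cols(0, n - 1) * x.subvec(0, n - 1);
  uvec basis(m);
  for (uword i = 0; i < m; ++i) {
    Aw(i, n + i) = (r(i) >= 0) ? 1.0 : -1.0;
    x(n + i) = std::fabs(r(i));
    basis(i) = n + i;
    vstat(n + i) = BASIC;
  }

  // phase 1: drive artificials to zero
  vec c1(n + m, fill::zeros);
  c1.subvec(n, n + m - 1).fill(-1.0);
  int st = run_phase(Aw, c1, lbw, ubw, basis, vstat, x, maxit);
  double infeas = accu(x.subvec(n, n + m - 1));
  if (st == 3)
    return Rcpp::List::create(Rcpp::Named("status") = 3,
                              Rcpp::Named("objective") = NA_REAL,
                              Rcpp::Named("x") = R_NilValue);
  if (infeas > FEAS_TOL * (1.0 + norm(b, "inf")))
    return Rcpp::List::create(Rcpp::Named("status") = 1,
                              Rcpp::Named("objective") = NA_REAL,
                              Rcpp::Named("x") = R_NilValue);

  // phase 2: pin artificials at zero and optimize the true objective
  ubw.subvec(n, n + m - 1).zeros();
  for (uword i = 0; i < m; ++i) {
    uword ai = n + i;
    if (vstat(ai) != BASIC) { vstat(ai) = AT_LB; x(ai) = 0; }
    else x(ai) = 0;  // basic at (numerically) zero stays pinned by bounds
  }
  vec c2(n + m, fill::zeros);
  c2.subvec(0, n - 1) = c;
  st = run_phase(Aw, c2, lbw, ubw, basis, vstat, x, maxit);
  if (st == 2)
    return Rcpp::List::create(Rcpp::Named("status") = 2,
                              Rcpp::Named("objective") = NA_REAL,
                              Rcpp::Named("x") = R_NilValue);
  if (st == 3)
    return Rcpp::List::create(Rcpp::Named("status") = 3,
                              Rcpp::Named("objective") = NA_REAL,
                              Rcpp::Named("x") = R_NilValue);

  vec xs = x.subvec(0, n - 1);
  double obj = dot(cobj, xs);
  return Rcpp::List::create(Rcpp::Named("status") = 0,
                            Rcpp::Named("objective") = obj,
                            Rcpp::Named("x") = xs);
}
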