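// Bounded-variable two-phase primal simplex, dense tableau.
//
// Sized for toy genome-scale networks (tens of metabolites x a few hundred
// reactions): the full tableau fits in cache and a pivot is O(m*N), so cold
// solves run in well under a millisecond and flux-variability sweeps can
// warm-start from the previous optimal basis (the basis stays feasible when
// only the objective changes, so phase 1 runs once per sweep).
//
// Robustness: artificial variables can never re-enter the basis, the ratio
// test is two-pass (shortest step first, then the largest pivot element
// among near-ties), the tableau is refactorized from the basis at regular
// intervals, and every reported optimum is verified against the original
// constraints; on verification failure the solve restarts from scratch
// under Bland's rule.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

const double BIG = 1e9;

enum Status { OPTIMAL = 0, INFEASIBLE = 1, UNBOUNDED = 2, ITLIMIT = 3 };

class BoundedSimplex {
public:
  arma::mat A;              // m x N, artificials appended after structurals
  arma::vec b, lb, ub, cost;
  int m, n, N;              // rows, structural cols, total cols
  arma::mat T;              // tableau: Binv * A
  arma::vec xB;             // values of basic variables
  std::vector<int> basis;   // basis[i] = variable in row i
  std::vector<int> vstat;   // 0 nonbasic at lb, 1 nonbasic at ub, 2 basic
  double feastol, pivtol;
  int status;
  long pivots, max_pivots;
  bool bland_always;

  BoundedSimplex(const arma::mat& As, const arma::vec& bs,
                 const arma::vec& lbs, const arma::vec& ubs,
                 bool bland = false)
    : feastol(1e-9), pivtol(1e-9), status(-1), pivots(0),
      bland_always(bland) {
    m = As.n_rows; n = As.n_cols; N = n + m;
    max_pivots = 20000L + 50L * (long)(m + n);
    A.zeros(m, N);
    A.cols(0, n - 1) = As;
    b = bs;
    lb.set_size(N); ub.set_size(N); cost.zeros(N);
    lb.subvec(0, n - 1) = lbs;
    ub.subvec(0, n - 1) = ubs;
    for (int j = 0; j < n; ++j) {
      if (!std::isfinite(lb[j])) lb[j] = -BIG;
      if (!std::isfinite(ub[j])) ub[j] = BIG;
    }
    basis.assign(m, 0); vstat.assign(N, 0);
  }

  double nbval(int j) const { return vstat[j] == 1 ? ub[j] : lb[j]; }

  arma::vec full_x() const {
    arma::vec x(N);
    for (int j = 0; j < N; ++j) if (vstat[j] != 2) x[j] = nbval(j);
    for (int i = 0; i < m; ++i) x[basis[i]] = xB[i];
    return x;
  }

  // Recompute tableau and basic values from scratch (numerical refresh).
  bool refactor() {
    arma::mat B(m, m);
    for (int i = 0; i < m; ++i) B.col(i) = A.col(basis[i]);
    arma::mat Binv;
    if (!arma::inv(Binv, B)) return false;
    T = Binv * A;
    arma::vec xn(N, arma::fill::zeros);
    for (int j = 0; j < N; ++j) if (vstat[j] != 2) xn[j] = nbval(j);
    xB = Binv * (b - A * xn);
    return true;
  }

  // Max violation of equality constraints and bounds by the current point.
  double primal_violation() const {
    arma::vec x = full_x();
    double v = arma::abs(A * x - b).max();
    for (int j = 0; j < N; ++j) {
      if (x[j] < lb[j]) v = std::max(v, lb[j] - x[j]);
      if (x[j] > ub[j]) v = std::max(v, x[j] - ub[j]);
    }
    return v;
  }

  void start_phase1() {
    for (int j = 0; j < n; ++j)
      vstat[j] = (std::abs(lb[j]) <= std::abs(ub[j])) ? 0 : 1;
    arma::vec xn(N, arma::fill::zeros);
    for (int j = 0; j < n; ++j) xn[j] = nbval(j);
    arma::vec r = b - A * xn;
    for (int i = 0; i < m; ++i) {
      double s = (r[i] >= 0) ? 1.0 : -1.0;
      A(i, n + i) = s;
      lb[n + i] = 0.0; ub[n + i] = BIG;
      basis[i] = n + i; vstat[n + i] = 2;
    }
    T = A;
    xB.set_size(m);
    for (int i = 0; i < m; ++i) {
      double s = A(i, n + i);
      if (s < 0) T.row(i) *= -1.0;
      xB[i] = std::abs(r[i]);
    }
  }

  // One phase of simplex on `c`; `allow` marks columns eligible to ENTER.
  int iterate(const arma::vec& c, const std::vector<bool>& allow) {
    int stall = 0;
    bool bland = bland_always;
    double last_obj = arma::datum::inf;
    long local_it = 0;
    while (true) {
      if (++local_it > max_pivots) return ITLIMIT;
      if (pivots > 0 && pivots % 100 == 0) refactor();
      arma::vec cB(m);
      for (int i = 0; i < m; ++i) cB[i] = c[basis[i]];
      arma::rowvec d = c.t() - cB.t() * T;
      int enter = -1; double best = 0.0;
      for (int j = 0; j < N; ++j) {
        if (vstat[j] == 2 || !allow[j]) continue;
        if (ub[j] - lb[j] < pivtol) continue;  // fixed variable
        double dj = d[j];
        double viol = 0.0;
        if (vstat[j] == 0 && dj < -feastol) viol = -dj;
        else if (vstat[j] == 1 && dj > feastol) viol = dj;
        if (viol > best + 1e-15) {
          best = viol; enter = j;
          if (bland) break;  // first eligible (Bland's rule)
        }
      }
      if (enter < 0) return OPTIMAL;
      double dir = (vstat[enter] == 0) ? 1.0 : -1.0;
      arma::vec y = T.col(enter);
      // ratio test, pass 1: shortest step
      double delta = ub[enter] - lb[enter];  // bound-flip limit
      for (int i = 0; i < m; ++i) {
        double coef = y[i] * dir;
        int bi = basis[i];
        double step;
        if (coef > pivtol) step = (xB[i] - lb[bi]) / coef;
        else if (coef < -pivtol) step = (ub[bi] - xB[i]) / (-coef);
        else continue;
        if (step < 0.0) step = 0.0;
        if (step < delta) delta = step;
      }
      // pass 2: among rows within tolerance of the shortest step, take the
      // one with the largest pivot magnitude (numerical stability); break
      // remaining ties by smallest variable index (determinism/Bland)
      int lrow = -1; int leave_to = 0; double bestpiv = 0.0;
      for (int i = 0; i < m; ++i) {
        double coef = y[i] * dir;
        int bi = basis[i];
        double step;
        if (coef > pivtol) step = (xB[i] - lb[bi]) / coef;
        else if (coef < -pivtol) step = (ub[bi] - xB[i]) / (-coef);
        else continue;
        if (step < 0.0) step = 0.0;
        if (step <= delta + 1e-9) {
          double mag = std::abs(coef);
          if (mag > bestpiv * (1.0 + 1e-9) ||
              (mag > bestpiv * (1.0 - 1e-9) && lrow >= 0 && bi < basis[lrow])) {
            bestpiv = mag; lrow = i; leave_to = (coef > 0) ? 0 : 1;
          }
        }
      }
      if (delta >= BIG) return UNBOUNDED;
      ++pivots;
      double objnow = arma::dot(cB, xB);
      if (objnow < last_obj - 1e-12) { last_obj = objnow; stall = 0; }
      else if (++stall > 2 * (m + 50)) bland = true;
      if (lrow < 0 || delta >= ub[enter] - lb[enter] - 1e-12) {
        // bound flip, no basis change
        double flip = ub[enter] - lb[enter];
        xB -= y * (flip * dir);
        vstat[enter] = 1 - vstat[enter];
        continue;
      }
      int leave = basis[lrow];
      xB -= y * (delta * dir);
      double enter_val = nbval(enter) + delta * dir;
      double piv = T(lrow, enter);
      T.row(lrow) /= piv;
      for (int i = 0; i < m; ++i) {
        if (i == lrow) continue;
        double f = T(i, enter);
        if (f != 0.0) T.row(i) -= f * T.row(lrow);
      }
      basis[lrow] = enter; vstat[enter] = 2;
      vstat[leave] = leave_to;
      xB[lrow] = enter_val;
    }
  }

  // Full solve: phase 1 then phase 2 on `obj` (minimisation).
  void solve(const arma::vec& obj_struct) {
    start_phase1();
    arma::vec c1(N, arma::fill::zeros);
    for (int i = 0; i < m; ++i) c1[n + i] = 1.0;
    std::vector<bool> allow(N, true);
    for (int j = n; j < N; ++j) allow[j] = false;  // artificials never enter
    int st = iterate(c1, allow);
    if (st == ITLIMIT) { status = ITLIMIT; return; }
    refactor();
    double art = 0.0;
    for (int i = 0; i < m; ++i) if (basis[i] >= n) art += std::abs(xB[i]);
    if (art > 1e-7) { status = INFEASIBLE; return; }
    pin_artificials();
    status = resolve(obj_struct);
  }

  void pin_artificials() {
    for (int j = n; j < N; ++j) { ub[j] = 0.0; if (vstat[j] == 1) vstat[j] = 0; }
    for (int i = 0; i < m; ++i) {
      if (basis[i] < n) continue;
      int piv = -1;
      double bestmag = 1e-7;
      for (int j = 0; j < n; ++j) {
        if (vstat[j] == 2) continue;
        double mag = std::abs(T(i, j));
        if (mag > bestmag) { bestmag = mag; piv = j; }
      }
      if (piv < 0) continue;  // redundant row: artificial stays basic at 0
      int leave = basis[i];
      double p = T(i, piv);
      T.row(i) /= p;
      for (int k = 0; k < m; ++k) {
        if (k == i) continue;
        double f = T(k, piv);
        if (f != 0.0) T.row(k) -= f * T.row(i);
      }
      basis[i] = piv; vstat[piv] = 2; vstat[leave] = 0;
      xB[i] = 0.0;
    }
    refactor();
  }

  // Re-optimise from the current (feasible) basis with a new objective.
  int resolve(const arma::vec& obj_struct) {
    cost.zeros();
    cost.subvec(0, n - 1) = obj_struct;
    std::vector<bool> allow(N, true);
    for (int j = n; j < N; ++j) allow[j] = false;
    int st = iterate(cost, allow);
    if (st == OPTIMAL) refactor();
    return st;
  }

  double objective() const {
    arma::vec x = full_x();
    return arma::dot(cost.subvec(0, n - 1), x.subvec(0, n - 1));
  }
};

// Solve with verification; on a numerically corrupt result, restart from
// scratch under Bland's rule before giving up.
int verified_solve(const arma::mat& A, const arma::vec& b,
                   const arma::vec& lb, const arma::vec& ub,
                   const arma::vec& cmin, arma::vec& x_out) {
  for (int attempt = 0; attempt < 2; ++attempt) {
    BoundedSimplex sx(A, b, lb, ub, attempt == 1);
    sx.solve(cmin);
    if (sx.status == INFEASIBLE || sx.status == UNBOUNDED) {
      if (attempt == 1) return sx.status;
      // cross-check claimed infeasibility/unboundedness once with Bland
      BoundedSimplex sx2(A, b, lb, ub, true);
      sx2.solve(cmin);
      if (sx2.status == OPTIMAL && sx2.primal_violation() < 1e-6) {
        x_out = sx2.full_x().subvec(0, A.n_cols - 1);
        return OPTIMAL;
      }
      return sx2.status;
    }
    if (sx.status == OPTIMAL && sx.primal_violation() < 1e-6) {
      x_out = sx.full_x().subvec(0, A.n_cols - 1);
      return OPTIMAL;
    }
    // corrupted or iteration-limited: retry deterministically with Bland
  }
  return ITLIMIT;
}

}  // namespace

// Solve  min/max c'x  s.t.  A x = b,  lb <= x <= ub.
// [[Rcpp::export(name = ".cpp_lp_solve")]]
List cpp_lp_solve(const arma::mat& A, const arma::vec& b,
                  const arma::vec& lb, const arma::vec& ub,
                  const arma::vec& obj, bool maximize) {
  arma::vec c = maximize ? arma::vec(-obj) : obj;
  arma::vec x(A.n_cols, arma::fill::value(NA_REAL));
  int status = verified_solve(A, b, lb, ub, c, x);
  double objval = NA_REAL;
  if (status == OPTIMAL) objval = arma::dot(obj, x);
  return List::create(_["status"] = status, _["objective"] = objval,
                      _["x"] = x);
}

// Min and max of each requested column, warm-starting between objectives.
// Falls back to a verified cold solve whenever a warm re-optimisation
// produces a numerically corrupt result.
// [[Rcpp::export(name = ".cpp_lp_sweep")]]
List cpp_lp_sweep(const arma::mat& A, const arma::vec& b,
                  const arma::vec& lb, const arma::vec& ub,
                  const IntegerVector& cols) {
  int n = A.n_cols;
  arma::vec zero(n, arma::fill::zeros);
  BoundedSimplex sx(A, b, lb, ub);
  sx.solve(zero);
  int k = cols.size();
  NumericVector vmin(k, NA_REAL), vmax(k, NA_REAL);
  if (sx.status != OPTIMAL || sx.primal_violation() > 1e-6) {
    // establishively verify feasibility via the fallback path
    arma::vec x(n);
    int st = verified_solve(A, b, lb, ub, zero, x);
    if (st != OPTIMAL) {
      return List::create(_["status"] = st, _["min"] = vmin, _["max"] = vmax);
    }
    sx = BoundedSimplex(A, b, lb, ub, true);
    sx.solve(zero);
  }
  int worst = OPTIMAL;
  for (int t = 0; t < k; ++t) {
    int j = cols[t] - 1;  // 1-based from R
    for (int sense = 0; sense < 2; ++sense) {
      arma::vec c(n, arma::fill::zeros);
      c[j] = sense == 0 ? 1.0 : -1.0;
      int st = sx.resolve(c);
      bool ok = st == OPTIMAL && sx.primal_violation() < 1e-6;
      double val = NA_REAL;
      if (ok) {
        val = sx.full_x()[j];
      } else {
        arma::vec x(n);
        int st2 = verified_solve(A, b, lb, ub, c, x);
        if (st2 == OPTIMAL) {
          val = x[j];
          // restore a clean warm-start state for the next objectives
          sx = BoundedSimplex(A, b, lb, ub, true);
          sx.solve(zero);
        } else {
          worst = st2;
        }
      }
      if (sense == 0) vmin[t] = val; else vmax[t] = val;
    }
  }
  return List::create(_["status"] = worst, _["min"] = vmin, _["max"] = vmax);
}
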