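#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Bounded-variable two-phase primal simplex on a dense tableau.
//
// Solves  min c'x  s.t.  A x (<=,=,>=) b,  lb <= x <= ub.
// Rows are turned into equalities with one slack each; rows whose slack
// cannot absorb the initial residual get an artificial variable, and a
// phase-1 problem minimises the artificial sum first.  Nonbasic variables
// sit at a finite bound; the ratio test allows bound flips.  Dantzig
// pricing with a Bland fallback after a run of degenerate pivots.

static const double INF = std::numeric_limits<double>::infinity();

enum Status { AT_LB = 0, AT_UB = 1, BASIC = 2 };

struct Simplex {
  int m, n_struct, n_total;
  std::vector<double> T;     // m x n_total tableau, column-major
  std::vector<double> xB;    // basic values
  std::vector<int> basis;    // basis[i] = column of row i
  std::vector<int> stat;     // per-column status
  std::vector<double> lb, ub, cost, zrow;
  std::vector<bool> is_artificial;
  double feas_tol = 1e-9, opt_tol = 1e-8, piv_tol = 1e-9;

  double& at(int i, int j) { return T[(size_t)j * m + i]; }

  double var_value(int j) {
    if (stat[j] == AT_LB) return lb[j];
    if (stat[j] == AT_UB) return ub[j];
    for (int i = 0; i < m; ++i) if (basis[i] == j) return xB[i];
    return 0.0;
  }

  // price all columns against current cost vector c
  void compute_zrow(const std::vector<double>& c) {
    std::vector<double> y(m);
    for (int i = 0; i < m; ++i) y[i] = c[basis[i]];
    for (int j = 0; j < n_total; ++j) {
      double z = 0.0;
      const double* col = &T[(size_t)j * m];
      for (int i = 0; i < m; ++i) z += y[i] * col[i];
      zrow[j] = c[j] - z;
    }
  }

  // one simplex phase; returns 0 optimal, 1 unbounded, 2 iteration limit
  int iterate(const std::vector<double>& c, bool phase1, int max_iter) {
    compute_zrow(c);
    int degen_run = 0;
    bool bland = false;
    for (int iter = 0; iter < max_iter; ++iter) {
      // entering
      int e = -1; double best = -opt_tol; int dir = 0;
      for (int j = 0; j < n_total; ++j) {
        if (stat[j] == BASIC) continue;
        if (!phase1 && is_artificial[j]) continue;
        double d = zrow[j];
        if (stat[j] == AT_LB && d < -opt_tol) {
          if (bland) { e = j; dir = +1; break; }
          if (d < best) { best = d; e = j; dir = +1; }
        } else if (stat[j] == AT_UB && d > opt_tol) {
          if (bland) { e = j; dir = -1; break; }
          if (-d < best) { best = -d; e = j; dir = -1; }
        }
      }
      if (e < 0) return 0; // optimal
      // ratio test
      double delta = (std::isfinite(ub[e]) && std::isfinite(lb[e])) ? ub[e] - lb[e] : INF;
      int r = -1; int leave_to = AT_LB;
      const double* ce = &T[(size_t)e * m];
      for (int i = 0; i < m; ++i) {
        double a = dir * ce[i];
        int bi = basis[i];
        if (a > piv_tol) {
          double room = xB[i] - lb[bi];
          double t = (room < 0 ? 0.0 : room) / a;
          if (t < delta - 1e-12 || (t < delta + 1e-12 && (r < 0 || (bland ? bi < basis[r] : std::fabs(ce[i]) > std::fabs(ce[r]))))) {
            delta = t; r = i; leave_to = AT_LB;
          }
        } else if (a < -piv_tol) {
          if (!std::isfinite(ub[bi])) continue;
          double room = ub[bi] - xB[i];
          double t = (room < 0 ? 0.0 : room) / (-a);
          if (t < delta - 1e-12 || (t < delta + 1e-12 && (r < 0 || (bland ? bi < basis[r] : std::fabs(ce[i]) > std::fabs(ce[r]))))) {
            delta = t; r = i; leave_to = AT_UB;
          }
        }
      }
      if (!std::isfinite(delta)) return 1; // unbounded
      if (delta < 1e-12) { if (++degen_run > 2 * (m + n_total)) bland = true; }
      else degen_run = 0;
      // update basic values
      if (delta > 0.0)
        for (int i = 0; i < m; ++i) xB[i] -= dir * ce[i] * delta;
      if (r < 0) { // bound flip
        stat[e] = (stat[e] == AT_LB) ? AT_UB : AT_LB;
        continue;
      }
      int lv = basis[r];
      double enter_val = (dir > 0 ? lb[e] : ub[e]) + dir * delta;
      // pivot: replace basis[r] by e
      double piv = at(r, e);
      double inv = 1.0 / piv;
      for (int j = 0; j < n_total; ++j) T[(size_t)j * m + r] *= inv;
      for (int j = 0; j < n_total; ++j) {
        double* cj = &T[(size_t)j * m];
        double f = cj[r];
        if (j == e || f == 0.0) continue;
        const double* pe = &T[(size_t)e * m];
        for (int i = 0; i < m; ++i) if (i != r) cj[i] -= f * pe[i];
      }
      // column e becomes unit vector
      {
        double* pe = &T[(size_t)e * m];
        for (int i = 0; i < m; ++i) pe[i] = (i == r) ? 1.0 : 0.0;
      }
      double fz = zrow[e];
      if (fz != 0.0) {
        for (int j = 0; j < n_total; ++j) zrow[j] -= fz * T[(size_t)j * m + r];
        zrow[e] = 0.0;
      }
      stat[lv] = leave_to;
      stat[e] = BASIC;
      basis[r] = e;
      xB[r] = enter_val;
      if ((iter & 63) == 0) Rcpp::checkUserInterrupt();
    }
    return 2;
  }
};

// [[Rcpp::export]]
List simplex_lp(NumericMatrix A, NumericVector b, IntegerVector dir,
                NumericVector obj, NumericVector lb_, NumericVector ub_,
                int max_iter = 100000) {
  int m = A.nrow(), n = A.ncol();
  Simplex S;
  S.m = m; S.n_struct = n;
  // columns: n structural + m slacks (+ artificials appended as needed)
  int n_slack = m;
  std::vector<double> lb(n + n_slack), ub(n + n_slack);
  for (int j = 0; j < n; ++j) {
    lb[j] = lb_[j];
    ub[j] = R_finite(ub_[j]) ? ub_[j] : INF;
  }
  for (int i = 0; i < m; ++i) {
    int j = n + i;
    if (dir[i] < 0) { lb[j] = 0.0; ub[j] = INF; }        // <=
    else if (dir[i] > 0) { lb[j] = -INF; ub[j] = 0.0; }  // >=
    else { lb[j] = 0.0; ub[j] = 0.0; }                   // ==
  }
  // initial nonbasic statuses for structurals: at a finite bound
  std::vector<int> stat(n + n_slack);
  std::vector<double> x0(n + n_slack, 0.0);
  for (int j = 0; j < n; ++j) {
    if (std::isfinite(lb[j])) { stat[j] = AT_LB; x0[j] = lb[j]; }
    else if (std::isfinite(ub[j])) { stat[j] = AT_UB; x0[j] = ub[j]; }
    else { stat[j] = AT_LB; x0[j] = 0.0; lb[j] = -INF; } // free var: treat 0 as pseudo-bound
  }
  // residuals with structurals at x0
  std::vector<double> resid(m);
  for (int i = 0; i < m; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += A(i, j) * x0[j];
    resid[i] = b[i] - s; // required slack value
  }
  // decide basis: slack if residual within slack bounds, else artificial
  std::vector<int> basis(m);
  std::vector<double> xB(m);
  std::vector<int> art_rows;
  for (int i = 0; i < m; ++i) {
    int sj = n + i;
    if (resid[i] >= lb[sj] - 1e-12 && resid[i] <= ub[sj] + 1e-12) {
      basis[i] = sj; xB[i] = resid[i]; stat[sj] = BASIC;
    } else {
      // slack pinned at nearest bound, artificial carries the rest
      double sv = (resid[i] < lb[sj]) ? lb[sj] : ub[sj];
      stat[sj] = (sv == lb[sj]) ? AT_LB : AT_UB;
      x0[sj] = sv;
      art_rows.push_back(i);
      basis[i] = -1; xB[i] = resid[i] - sv; // signed for now
    }
  }
  int n_art = (int)art_rows.size();
  int n_total = n + n_slack + n_art;
  S.n_total = n_total;
  S.T.assign((size_t)n_total * m, 0.0);
  S.lb.assign(lb.begin(), lb.end()); S.lb.resize(n_total, 0.0);
  S.ub.assign(ub.begin(), ub.end()); S.ub.resize(n_total, INF);
  S.stat = stat; S.stat.resize(n_total, AT_LB);
  S.is_artificial.assign(n_total, false);
  S.basis = basis; S.xB = xB;
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) S.at(i, j) = A(i, j);
  for (int i = 0; i < m; ++i) S.at(i, n + i) = 1.0;
  for (int k = 0; k < n_art; ++k) {
    int i = art_rows[k];
    int j = n + n_slack + k;
    double sign = (S.xB[i] >= 0) ? 1.0 : -1.0;
    S.at(i, j) = sign;
    S.xB[i] = std::fabs(S.xB[i]);
    S.basis[i] = j;
    S.stat[j] = BASIC;
    S.is_artificial[j] = true;
    S.ub[j] = INF; S.lb[j] = 0.0;
    // tableau row must reflect basis = artificial: divide row by sign
    if (sign < 0)
      for (int jj = 0; jj < n_total; ++jj) if (jj != j) S.T[(size_t)jj * m + i] *= -1.0;
    // note b side already folded into xB
  }
  S.zrow.assign(n_total, 0.0);
  int status;
  if (n_art > 0) {
    std::vector<double> c1(n_total, 0.0);
    for (int j = n + n_slack; j < n_total; ++j) c1[j] = 1.0;
    status = S.iterate(c1, true, max_iter);
    double p1 = 0.0;
    for (int i = 0; i < m; ++i) if (S.is_artificial[S.basis[i]]) p1 += S.xB[i];
    if (status != 0 || p1 > 1e-7)
      return List::create(_["status"] = (p1 > 1e-7 ? "infeasible" : "error"),
                          _["objective"] = NA_REAL, _["x"] = R_NilValue);
    // pin artificials at zero so they never re-enter
    for (int j = n + n_slack; j < n_total; ++j)
      if (S.stat[j] != BASIC) { S.ub[j] = 0.0; S.stat[j] = AT_LB; }
      else S.ub[j] = 0.0; // basic at ~0; ratio test keeps it there
  }
  std::vector<double> c2(n_total, 0.0);
  for (int j = 0; j < n; ++j) c2[j] = obj[j];
  status = S.iterate(c2, false, max_iter);
  if (status != 0)
    return List::create(_["status"] = (status == 1 ? "unbounded" : "iteration_limit"),
                        _["objective"] = NA_REAL, _["x"] = R_NilValue);
  NumericVector x(n);
  for (int j = 0; j < n; ++j) x[j] = S.var_value(j);
  // clean tiny negatives / clip to bounds
  for (int j = 0; j < n; ++j) {
    if (x[j] < lb_[j]) x[j] = lb_[j];
    if (R_finite(ub_[j]) && x[j] > ub_[j]) x[j] = ub_[j];
  }
  double objval = 0.0;
  for (int j = 0; j < n; ++j) objval += obj[j] * x[j];
  return List::create(_["status"] = "optimal", _["objective"] = objval, _["x"] = x);
}
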