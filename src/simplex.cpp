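// Bounded-variable two-phase primal simplex for the linear programs behind
// flux balance analysis:
//
//     max / min  c'x   s.t.   A x = b,   lb <= x <= ub
//
// Inequality rows are the caller's responsibility (add explicit slack
// columns).  Revised simplex with sparse column storage for pricing, an
// explicitly maintained dense basis inverse with periodic refactorisation,
// bound flips, and a Bland's-rule fallback when the Dantzig rule stalls on
// degenerate vertices.  A batch entry point re-solves the same feasible
// region under a sequence of objectives (flux variability analysis) without
// repeating phase 1.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

const double PIVOT_TOL = 1e-8;
const double DUAL_TOL = 1e-9;
const double FEAS_TOL = 1e-8;
const int REFACTOR_EVERY = 60;

enum VStat { BASIC = 0, AT_LB = 1, AT_UB = 2, NB_FREE = 3 };

struct SimplexState {
  // sparse column storage of [structurals | artificials]
  std::vector<std::vector<int>> cidx;
  std::vector<std::vector<double>> cval;
  vec b;
  vec lb, ub;
  vec x;
  ivec basis;
  std::vector<int> stat;
  mat Binv;
  int m, n, ncol;
  int updates_since_refactor;

  vec col_times(const mat &M, int j) const {  // M * A.col(j) for m x m M
    vec out(m, fill::zeros);
    const std::vector<int> &ix = cidx[j];
    const std::vector<double> &vv = cval[j];
    for (size_t k = 0; k < ix.size(); ++k) out += M.col(ix[k]) * vv[k];
    return out;
  }
  double col_dot(const vec &y, int j) const {  // y . A.col(j)
    double s = 0.0;
    const std::vector<int> &ix = cidx[j];
    const std::vector<double> &vv = cval[j];
    for (size_t k = 0; k < ix.size(); ++k) s += y[ix[k]] * vv[k];
    return s;
  }
};

void refactor(SimplexState &S) {
  mat B(S.m, S.m, fill::zeros);
  for (int i = 0; i < S.m; ++i) {
    int j = S.basis[i];
    for (size_t k = 0; k < S.cidx[j].size(); ++k)
      B(S.cidx[j][k], i) = S.cval[j][k];
  }
  bool ok = inv(S.Binv, B);
  if (!ok) Rcpp::stop("simplex: basis matrix singular during refactorisation");
  vec rhs = S.b;
  for (int j = 0; j < S.ncol; ++j)
    if (S.stat[j] != BASIC && S.x[j] != 0.0)
      for (size_t k = 0; k < S.cidx[j].size(); ++k)
        rhs[S.cidx[j][k]] -= S.cval[j][k] * S.x[j];
  vec xB = S.Binv * rhs;
  for (int i = 0; i < S.m; ++i) S.x[S.basis[i]] = xB[i];
  S.updates_since_refactor = 0;
}

// one simplex phase on objective `cost`; returns 0 optimal, 2 unbounded,
// 3 iteration limit
int run_phase(SimplexState &S, const vec &cost, int max_iter) {
  int iter = 0, stall = 0;
  bool bland = false;
  double last_obj = datum::inf;

  while (iter++ < max_iter) {
    vec cB(S.m);
    for (int i = 0; i < S.m; ++i) cB[i] = cost[S.basis[i]];
    vec y = S.Binv.t() * cB;

    // pricing (minimisation)
    int q = -1, q_dir = 0;
    double best = -DUAL_TOL;
    for (int j = 0; j < S.ncol; ++j) {
      if (S.stat[j] == BASIC) continue;
      double dj = cost[j] - S.col_dot(y, j);
      int dir = 0;
      double score = 0.0;
      if ((S.stat[j] == AT_LB || S.stat[j] == NB_FREE) && dj < -DUAL_TOL) {
        score = dj; dir = +1;
      } else if ((S.stat[j] == AT_UB || S.stat[j] == NB_FREE) && dj > DUAL_TOL) {
        score = -dj; dir = -1;
      }
      if (dir == 0) continue;
      if (bland) { q = j; q_dir = dir; break; }
      if (score < best) { best = score; q = j; q_dir = dir; }
    }
    if (q < 0) return 0;  // optimal

    vec w = S.col_times(S.Binv, q);

    // ratio test on x_B(t) = x_B - q_dir t w, x_q(t) = x_q + q_dir t
    std::vector<double> step(S.m, datum::inf);
    std::vector<int> hit(S.m, 0);
    double own_range = datum::inf;
    if ((S.stat[q] == AT_LB || S.stat[q] == AT_UB) &&
        std::isfinite(S.lb[q]) && std::isfinite(S.ub[q]))
      own_range = S.ub[q] - S.lb[q];
    double t_min = own_range;

    for (int i = 0; i < S.m; ++i) {
      double wi = q_dir * w[i];
      int bi = S.basis[i];
      if (wi > PIVOT_TOL && std::isfinite(S.lb[bi])) {
        step[i] = std::max((S.x[bi] - S.lb[bi]) / wi, 0.0);
        hit[i] = AT_LB;
      } else if (wi < -PIVOT_TOL && std::isfinite(S.ub[bi])) {
        step[i] = std::max((S.ub[bi] - S.x[bi]) / (-wi), 0.0);
        hit[i] = AT_UB;
      }
      if (step[i] < t_min) t_min = step[i];
    }

    if (!std::isfinite(t_min)) return 2;  // unbounded

    int leave = -1, leave_bound = 0;
    if (t_min < own_range - 1e-12 || !std::isfinite(own_range)) {
      double best_piv = 0.0;
      for (int i = 0; i < S.m; ++i) {
        if (hit[i] == 0 || step[i] > t_min + 1e-12) continue;
        if (bland) {
          if (leave < 0 || S.basis[i] < S.basis[leave]) { leave = i; leave_bound = hit[i]; }
        } else if (std::fabs(w[i]) > best_piv) {
          best_piv = std::fabs(w[i]); leave = i; leave_bound = hit[i];
        }
      }
    }
    double t_max = (leave >= 0) ? step[leave] : own_range;

    for (int i = 0; i < S.m; ++i) S.x[S.basis[i]] -= q_dir * t_max * w[i];
    S.x[q] += q_dir * t_max;

    if (leave < 0) {
      // bound flip
      S.stat[q] = (S.stat[q] == AT_LB) ? AT_UB : AT_LB;
      S.x[q] = (S.stat[q] == AT_LB) ? S.lb[q] : S.ub[q];
    } else {
      int out = S.basis[leave];
      S.stat[out] = leave_bound;
      S.x[out] = (leave_bound == AT_LB) ? S.lb[out] : S.ub[out];
      S.basis[leave] = q;
      S.stat[q] = BASIC;
      double piv = w[leave];
      if (std::fabs(piv) < PIVOT_TOL) {
        refactor(S);
      } else {
        rowvec pivrow = S.Binv.row(leave) / piv;
        for (int i = 0; i < S.m; ++i) {
          if (i == leave || w[i] == 0.0) continue;
          S.Binv.row(i) -= w[i] * pivrow;
        }
        S.Binv.row(leave) = pivrow;
        if (++S.updates_since_refactor >= REFACTOR_EVERY) refactor(S);
      }
    }

    double obj = 0.0;
    for (int i = 0; i < S.m; ++i) obj += cost[S.basis[i]] * S.x[S.basis[i]];
    for (int j = 0; j < S.ncol; ++j)
      if (S.stat[j] != BASIC && cost[j] != 0.0 && S.x[j] != 0.0) obj += cost[j] * S.x[j];
    if (obj < last_obj - 1e-10 * (1.0 + std::fabs(last_obj))) {
      last_obj = obj; stall = 0; bland = false;
    } else if (++stall > 200) {
      bland = true;
    }
  }
  return 3;
}

// initialise state from R inputs and run phase 1; returns simplex status
int prepare(SimplexState &S, const mat &A_in, const vec &b_in,
            const vec &lb_in, const vec &ub_in, vec &scale, int max_iter) {
  const int m = A_in.n_rows, n = A_in.n_cols;
  S.m = m; S.n = n; S.ncol = n + m;

  scale.ones(n);
  for (int j = 0; j < n; ++j) {
    double mx = 0.0;
    for (int i = 0; i < m; ++i) mx = std::max(mx, std::fabs(A_in(i, j)));
    if (mx > 0 && (mx > 16.0 || mx < 1.0 / 16.0)) scale[j] = mx;
  }

  S.cidx.assign(S.ncol, {});
  S.cval.assign(S.ncol, {});
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < m; ++i) {
      double v = A_in(i, j);
      if (v != 0.0) { S.cidx[j].push_back(i); S.cval[j].push_back(v / scale[j]); }
    }
  }
  S.b = b_in;
  S.lb.set_size(S.ncol); S.ub.set_size(S.ncol);
  for (int j = 0; j < n; ++j) {
    S.lb[j] = std::isfinite(lb_in[j]) ? lb_in[j] * scale[j] : -datum::inf;
    S.ub[j] = std::isfinite(ub_in[j]) ? ub_in[j] * scale[j] : datum::inf;
    if (S.lb[j] > S.ub[j] + 1e-9) return 1;
  }
  S.x.zeros(S.ncol);
  S.stat.assign(S.ncol, AT_LB);
  for (int j = 0; j < n; ++j) {
    bool lf = std::isfinite(S.lb[j]), uf = std::isfinite(S.ub[j]);
    if (lf && uf) {
      if (std::fabs(S.lb[j]) <= std::fabs(S.ub[j])) { S.stat[j] = AT_LB; S.x[j] = S.lb[j]; }
      else { S.stat[j] = AT_UB; S.x[j] = S.ub[j]; }
    } else if (lf) { S.stat[j] = AT_LB; S.x[j] = S.lb[j]; }
    else if (uf) { S.stat[j] = AT_UB; S.x[j] = S.ub[j]; }
    else { S.stat[j] = NB_FREE; S.x[j] = 0.0; }
  }

  vec resid = S.b;
  for (int j = 0; j < n; ++j)
    if (S.x[j] != 0.0)
      for (size_t k = 0; k < S.cidx[j].size(); ++k)
        resid[S.cidx[j][k]] -= S.cval[j][k] * S.x[j];

  S.basis.set_size(m);
  S.Binv.eye(m, m);
  for (int i = 0; i < m; ++i) {
    int aj = n + i;
    double sgn = (resid[i] >= 0) ? 1.0 : -1.0;
    S.cidx[aj] = {i};
    S.cval[aj] = {sgn};
    S.lb[aj] = 0.0; S.ub[aj] = datum::inf;
    S.x[aj] = std::fabs(resid[i]);
    S.basis[i] = aj;
    S.stat[aj] = BASIC;
    S.Binv(i, i) = sgn;
  }
  S.updates_since_refactor = 0;

  vec cost1(S.ncol, fill::zeros);
  for (int i = 0; i < m; ++i) cost1[n + i] = 1.0;
  double art0 = accu(S.x.subvec(n, S.ncol - 1));
  if (art0 > FEAS_TOL) {
    int st = run_phase(S, cost1, max_iter);
    if (st == 3) return 3;
    double art = 0.0;
    for (int i = 0; i < m; ++i) art += S.x[n + i];
    if (art > FEAS_TOL * (1.0 + norm(S.b, "inf"))) return 1;
  }
  for (int i = 0; i < m; ++i) { S.lb[n + i] = 0.0; S.ub[n + i] = 0.0; }
  return 0;
}

}  // namespace

// [[Rcpp::export(name = ".simplex_solve")]]
Rcpp::List simplex_solve(const arma::mat &A_in, const arma::vec &b_in,
                         const arma::vec &c_in, const arma::vec &lb_in,
                         const arma::vec &ub_in, bool maximize,
                         int max_iter = 0) {
  const int m = A_in.n_rows, n = A_in.n_cols;
  if (max_iter <= 0) max_iter = 200 * (m + n) + 20000;
  SimplexState S;
  vec scale;
  int st = prepare(S, A_in, b_in, lb_in, ub_in, scale, max_iter);
  if (st == 0) {
    vec cost2(S.ncol, fill::zeros);
    for (int j = 0; j < n; ++j) cost2[j] = (maximize ? -c_in[j] : c_in[j]) / scale[j];
    st = run_phase(S, cost2, max_iter);
  }
  if (st != 0)
    return Rcpp::List::create(Rcpp::Named("status") = st,
                              Rcpp::Named("x") = R_NilValue,
                              Rcpp::Named("objective") = R_NilValue);
  vec xout(n);
  for (int j = 0; j < n; ++j) xout[j] = S.x[j] / scale[j];
  double obj = dot(c_in, xout);
  return Rcpp::List::create(Rcpp::Named("status") = 0,
                            Rcpp::Named("x") = xout,
                            Rcpp::Named("objective") = obj);
}

// Batch flux variability: maximise c_base once, tighten the floor variable
// `floor_col` (1-based) to frac * optimum via its lower bound (the current
// solution stays feasible), then min- and maximise each requested column
// re-using the warm basis.
// [[Rcpp::export(name = ".simplex_fva")]]
Rcpp::List simplex_fva(const arma::mat &A_in, const arma::vec &b_in,
                       const arma::vec &c_in, const arma::vec &lb_in,
                       const arma::vec &ub_in, int floor_col, double frac,
                       const arma::ivec &cols, int max_iter = 0) {
  const int m = A_in.n_rows, n = A_in.n_cols;
  if (max_iter <= 0) max_iter = 200 * (m + n) + 20000;
  SimplexState S;
  vec scale;
  int st = prepare(S, A_in, b_in, lb_in, ub_in, scale, max_iter);
  if (st == 0) {
    vec cost(S.ncol, fill::zeros);
    for (int j = 0; j < n; ++j) cost[j] = -c_in[j] / scale[j];  // maximise
    st = run_phase(S, cost, max_iter);
  }
  if (st != 0)
    return Rcpp::List::create(Rcpp::Named("status") = st);
  double zopt = 0.0;
  for (int j = 0; j < n; ++j) zopt += c_in[j] * S.x[j] / scale[j];

  // tighten floor: lb on the floor column (scaled space)
  int fc = floor_col - 1;
  double floor_val = frac * zopt;
  if (zopt < 0) floor_val = zopt * (2.0 - frac);  // keep floor below optimum
  S.lb[fc] = floor_val * scale[fc];

  const int K = cols.n_elem;
  vec vmin(K), vmax(K);
  for (int k = 0; k < K; ++k) {
    int j = cols[k] - 1;
    vec cost(S.ncol, fill::zeros);
    cost[j] = 1.0;  // minimise
    int st1 = run_phase(S, cost, max_iter);
    if (st1 == 2) vmin[k] = -datum::inf;
    else if (st1 != 0) return Rcpp::List::create(Rcpp::Named("status") = st1);
    else vmin[k] = S.x[j] / scale[j];
    cost[j] = -1.0;  // maximise
    int st2 = run_phase(S, cost, max_iter);
    if (st2 == 2) vmax[k] = datum::inf;
    else if (st2 != 0) return Rcpp::List::create(Rcpp::Named("status") = st2);
    else vmax[k] = S.x[j] / scale[j];
  }
  return Rcpp::List::create(Rcpp::Named("status") = 0,
                            Rcpp::Named("min") = vmin,
                            Rcpp::Named("max") = vmax,
                            Rcpp::Named("optimum") = zopt);
}
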