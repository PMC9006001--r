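// Binary-state speciation/extinction (BiSSE) likelihood core with rates
// piecewise-constant across geological epochs.
//
// State vector y = (E0, E1, D0, D1):
//   E_i(a): probability a lineage in state i at age a leaves no sampled
//           descendants at the present;
//   D_i(a): probability density of the observed subtree given the lineage is
//           in state i at age a.
// Backward ODEs in age a (rates constant within an epoch):
//   dE_i/da = mu_i - (la_i + mu_i + q_ij) E_i + la_i E_i^2 + q_ij E_j
//   dD_i/da = -(la_i + mu_i + q_ij) D_i + q_ij D_j + 2 la_i E_i D_i
//
// Integration is split exactly at every epoch boundary crossed, so rate
// discontinuities never straddle a step. D is rescaled into a log
// accumulator whenever max(D) leaves [1e-12, 1e12].

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// pars = (la0, la1, mu0, mu1, q01, q10) for one epoch
static inline void bisse_deriv(const double* y, double* dy, const double* p) {
  const double la0 = p[0], la1 = p[1], mu0 = p[2], mu1 = p[3],
               q01 = p[4], q10 = p[5];
  const double E0 = y[0], E1 = y[1], D0 = y[2], D1 = y[3];
  dy[0] = mu0 - (la0 + mu0 + q01) * E0 + la0 * E0 * E0 + q01 * E1;
  dy[1] = mu1 - (la1 + mu1 + q10) * E1 + la1 * E1 * E1 + q10 * E0;
  dy[2] = -(la0 + mu0 + q01) * D0 + q01 * D1 + 2.0 * la0 * E0 * D0;
  dy[3] = -(la1 + mu1 + q10) * D1 + q10 * D0 + 2.0 * la1 * E1 * D1;
}

// Cash-Karp embedded RK45 coefficients
static const double CK_A2 = 0.2, CK_A3 = 0.3, CK_A4 = 0.6, CK_A5 = 1.0,
                    CK_A6 = 0.875;
static const double B21 = 0.2;
static const double B31 = 3.0 / 40.0, B32 = 9.0 / 40.0;
static const double B41 = 0.3, B42 = -0.9, B43 = 1.2;
static const double B51 = -11.0 / 54.0, B52 = 2.5, B53 = -70.0 / 27.0,
                    B54 = 35.0 / 27.0;
static const double B61 = 1631.0 / 55296.0, B62 = 175.0 / 512.0,
                    B63 = 575.0 / 13824.0, B64 = 44275.0 / 110592.0,
                    B65 = 253.0 / 4096.0;
static const double C1 = 37.0 / 378.0, C3 = 250.0 / 621.0, C4 = 125.0 / 594.0,
                    C6 = 512.0 / 1771.0;
static const double DC1 = C1 - 2825.0 / 27648.0, DC3 = C3 - 18575.0 / 48384.0,
                    DC4 = C4 - 13525.0 / 55296.0, DC5 = -277.0 / 14336.0,
                    DC6 = C6 - 0.25;

// One constant-rate segment [t0, t1]; y updated in place, log rescalings of
// (D0, D1) accumulated into *logcomp.  Returns false on step-size failure.
static bool integrate_segment(double* y, double t0, double t1,
                              const double* p, double rtol, double atol,
                              double* logcomp) {
  const double span = t1 - t0;
  if (span <= 0.0) return true;
  double t = t0;
  double h = span;        // mild dynamics: try the whole segment first
  double k1[4], k2[4], k3[4], k4[4], k5[4], k6[4], ytmp[4], yerr[4], ynew[4];
  const int max_steps = 1000000;
  for (int step = 0; step < max_steps; ++step) {
    if (t >= t1) return true;
    if (t + h > t1) h = t1 - t;
    bisse_deriv(y, k1, p);
    for (int i = 0; i < 4; ++i) ytmp[i] = y[i] + h * B21 * k1[i];
    bisse_deriv(ytmp, k2, p);
    for (int i = 0; i < 4; ++i)
      ytmp[i] = y[i] + h * (B31 * k1[i] + B32 * k2[i]);
    bisse_deriv(ytmp, k3, p);
    for (int i = 0; i < 4; ++i)
      ytmp[i] = y[i] + h * (B41 * k1[i] + B42 * k2[i] + B43 * k3[i]);
    bisse_deriv(ytmp, k4, p);
    for (int i = 0; i < 4; ++i)
      ytmp[i] = y[i] + h * (B51 * k1[i] + B52 * k2[i] + B53 * k3[i] +
                            B54 * k4[i]);
    bisse_deriv(ytmp, k5, p);
    for (int i = 0; i < 4; ++i)
      ytmp[i] = y[i] + h * (B61 * k1[i] + B62 * k2[i] + B63 * k3[i] +
                            B64 * k4[i] + B65 * k5[i]);
    bisse_deriv(ytmp, k6, p);
    double errmax = 0.0;
    for (int i = 0; i < 4; ++i) {
      ynew[i] = y[i] + h * (C1 * k1[i] + C3 * k3[i] + C4 * k4[i] + C6 * k6[i]);
      yerr[i] = h * (DC1 * k1[i] + DC3 * k3[i] + DC4 * k4[i] + DC5 * k5[i] +
                     DC6 * k6[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double e = std::fabs(yerr[i]) / sc;
      if (e > errmax) errmax = e;
    }
    if (errmax <= 1.0) {
      t += h;
      for (int i = 0; i < 4; ++i) y[i] = ynew[i];
      // keep E inside [0,1] and D nonnegative against roundoff
      for (int i = 0; i < 2; ++i) {
        if (y[i] < 0.0) y[i] = 0.0;
        if (y[i] > 1.0) y[i] = 1.0;
        if (y[i + 2] < 0.0) y[i + 2] = 0.0;
      }
      double dmax = std::max(std::fabs(y[2]), std::fabs(y[3]));
      if (dmax > 0.0 && (dmax < 1e-12 || dmax > 1e12)) {
        y[2] /= dmax; y[3] /= dmax;
        *logcomp += std::log(dmax);
      }
      double fac = (errmax > 0.0) ? 0.9 * std::pow(errmax, -0.2) : 5.0;
      if (fac > 5.0) fac = 5.0;
      h *= fac;
    } else {
      double fac = 0.9 * std::pow(errmax, -0.25);
      if (fac < 0.1) fac = 0.1;
      h *= fac;
      if (h < 1e-14 * span) return false;
    }
  }
  return false;
}

// 0-based epoch row of an age.  Boundaries are sorted decreasing and rows of
// `pars` are ordered oldest epoch first; an age exactly on a boundary belongs
// to the OLDER epoch, matching epochs (root..66], (66..40], (40..0].
// Example, b = (66, 40): age 70 -> row 0; 66 -> row 0; 50 -> row 1;
// 40 -> row 1; 10 -> row 2.
static inline int epoch_index_c(double age, const NumericVector& bounds) {
  int younger = 0;  // boundaries strictly greater than age
  for (int i = 0; i < bounds.size(); ++i)
    if (bounds[i] > age) ++younger;
  return younger;  // 0 boundaries above -> oldest epoch -> row 0
}

// Integrate one branch from age_lo up to age_hi, splitting at epoch
// boundaries.  pars: nep x 6 matrix, rows oldest-first is NOT assumed here;
// rows are indexed by epoch_index_c, i.e. row 0 = oldest epoch.
static bool integrate_branch_c(double* y, double age_lo, double age_hi,
                               const NumericMatrix& pars,
                               const NumericVector& bounds,
                               double rtol, double atol, double* logcomp) {
  // collect boundaries strictly inside (age_lo, age_hi), ascending
  std::vector<double> cuts;
  for (int i = bounds.size() - 1; i >= 0; --i)
    if (bounds[i] > age_lo && bounds[i] < age_hi) cuts.push_back(bounds[i]);
  std::sort(cuts.begin(), cuts.end());
  double lo = age_lo;
  double prow[6];
  for (size_t k = 0; k <= cuts.size(); ++k) {
    double hi = (k < cuts.size()) ? cuts[k] : age_hi;
    int e = epoch_index_c(0.5 * (lo + hi), bounds);
    for (int j = 0; j < 6; ++j) prow[j] = pars(e, j);
    if (!integrate_segment(y, lo, hi, prow, rtol, atol, logcomp))
      return false;
    lo = hi;
  }
  return true;
}

// [[Rcpp::export]]
List bisse_branch_cpp(NumericVector y0, double age_lo, double age_hi,
                      NumericMatrix pars, NumericVector bounds,
                      double rtol, double atol) {
  if (y0.size() != 4) stop("y0 must be (E0, E1, D0, D1)");
  if (age_lo >= age_hi) stop("need age_lo < age_hi");
  double y[4] = {y0[0], y0[1], y0[2], y0[3]};
  double logcomp = 0.0;
  if (!integrate_branch_c(y, age_lo, age_hi, pars, bounds, rtol, atol,
                          &logcomp))
    stop("BiSSE ODE solver failed to meet tolerance on [%g, %g]",
         age_lo, age_hi);
  return List::create(_["y"] = NumericVector::create(y[0], y[1], y[2], y[3]),
                      _["log_scale"] = logcomp);
}

// Full post-order pruning pass.
// edge: (2N-2) x 2 matrix of (parent, child) node indices, 1-based, in
//   postorder (every child edge appears before its parent's edge).
// ages: node ages indexed 1..(2N-1), tips first.
// tip_state: per tip 0, 1, or NA (unknown).
// Returns root (E0, E1, D0, D1) AFTER multiplying lambda at every internal
// node including the root, plus the accumulated log scaling.
// [[Rcpp::export]]
List bisse_prune_cpp(IntegerMatrix edge, NumericVector ages,
                     IntegerVector tip_state, NumericMatrix pars,
                     NumericVector bounds, double f0, double f1,
                     double rtol, double atol) {
  const int ntip = tip_state.size();
  const int nnode = ages.size();
  std::vector<double> E0(nnode), E1(nnode), D0(nnode), D1(nnode);
  std::vector<bool> seen(nnode, false);
  double logcomp = 0.0;

  // tip initial conditions
  for (int i = 0; i < ntip; ++i) {
    E0[i] = 1.0 - f0;
    E1[i] = 1.0 - f1;
    if (tip_state[i] == NA_INTEGER) { D0[i] = f0; D1[i] = f1; }
    else if (tip_state[i] == 0) { D0[i] = f0; D1[i] = 0.0; }
    else if (tip_state[i] == 1) { D0[i] = 0.0; D1[i] = f1; }
    else stop("tip states must be 0, 1 or NA");
    seen[i] = true;
  }

  std::vector<bool> has_child(nnode, false);
  int root = -1;
  for (int k = 0; k < edge.nrow(); ++k) {
    int par = edge(k, 0) - 1, ch = edge(k, 1) - 1;
    if (!seen[ch])
      stop("edges are not in postorder: child %d not ready", ch + 1);
    double y[4] = {E0[ch], E1[ch], D0[ch], D1[ch]};
    if (!integrate_branch_c(y, ages[ch], ages[par], pars, bounds, rtol, atol,
                            &logcomp))
      stop("BiSSE ODE solver failed on branch to node %d", ch + 1);
    if (!has_child[par]) {
      E0[par] = y[0]; E1[par] = y[1]; D0[par] = y[2]; D1[par] = y[3];
      has_child[par] = true;
    } else {
      // combine: D_i <- D_i^left * D_i^right * lambda_i(epoch of node age)
      int e = epoch_index_c(ages[par], bounds);
      D0[par] = D0[par] * y[2] * pars(e, 0);
      D1[par] = D1[par] * y[3] * pars(e, 1);
      seen[par] = true;
      double dmax = std::max(std::fabs(D0[par]), std::fabs(D1[par]));
      if (dmax > 0.0) {
        D0[par] /= dmax; D1[par] /= dmax;
        logcomp += std::log(dmax);
      }
    }
    root = par;
  }
  if (root < 0) stop("tree has no edges");
  return List::create(
    _["E"] = NumericVector::create(E0[root], E1[root]),
    _["D"] = NumericVector::create(D0[root], D1[root]),
    _["log_scale"] = logcomp,
    _["root_age"] = ages[root]);
}
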