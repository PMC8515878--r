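#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// State-dependent birth-death pruning core.
//
// Per combined state i the clade likelihood D_i and the extinction /
// non-sampling probability E_i evolve rootward along a branch as
//   dE_i/dt = mu_i - (lambda_i + mu_i) E_i + sum_j Q_ij E_j + lambda_i E_i^2
//   dD_i/dt = -(lambda_i + mu_i) D_i + sum_j Q_ij D_j + 2 lambda_i E_i D_i
// with Q a rate matrix whose rows sum to zero (diagonal included).
// Both systems are integrated jointly with an adaptive Dormand-Prince 5(4)
// scheme; D is log-rescaled when it underflows.

struct SSEPars {
  int n;
  const double *lambda, *mu, *Q; // Q column-major n x n, rows sum to 0
};

static inline void sse_rhs(const SSEPars &p, const double *y, double *dy) {
  const int n = p.n;
  const double *E = y, *D = y + n;
  double *dE = dy, *dD = dy + n;
  if (n == 2) { // dominant case: observed states only
    const double q01 = p.Q[2], q10 = p.Q[1]; // column-major off-diagonals
    const double lm0 = p.lambda[0] + p.mu[0], lm1 = p.lambda[1] + p.mu[1];
    dE[0] = p.mu[0] - (lm0 + q01) * E[0] + q01 * E[1] +
            p.lambda[0] * E[0] * E[0];
    dE[1] = p.mu[1] - (lm1 + q10) * E[1] + q10 * E[0] +
            p.lambda[1] * E[1] * E[1];
    dD[0] = -(lm0 + q01) * D[0] + q01 * D[1] +
            2.0 * p.lambda[0] * E[0] * D[0];
    dD[1] = -(lm1 + q10) * D[1] + q10 * D[0] +
            2.0 * p.lambda[1] * E[1] * D[1];
    return;
  }
  for (int i = 0; i < n; ++i) {
    double qe = 0.0, qd = 0.0;
    for (int j = 0; j < n; ++j) {
      const double qij = p.Q[i + j * n];
      qe += qij * E[j];
      qd += qij * D[j];
    }
    const double lm = p.lambda[i] + p.mu[i];
    dE[i] = p.mu[i] - lm * E[i] + qe + p.lambda[i] * E[i] * E[i];
    dD[i] = -lm * D[i] + qd + 2.0 * p.lambda[i] * E[i] * D[i];
  }
}

// Dormand-Prince 5(4) tableau.
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                    e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

// Scratch space shared across branch integrations of one tree pass.
struct SSEWork {
  std::vector<double> k1, k2, k3, k4, k5, k6, k7, yt, ynew;
  explicit SSEWork(int m)
      : k1(m), k2(m), k3(m), k4(m), k5(m), k6(m), k7(m), yt(m), ynew(m) {}
};

// Integrate y (length 2n) over duration t.  Returns accumulated log scale
// factored out of D.  Throws on step-size collapse.
static double integrate_branch(const SSEPars &p, double *y, double t,
                               double rtol, double atol, SSEWork &w) {
  const int n = p.n, m = 2 * p.n;
  if (t <= 0.0) return 0.0;
  std::vector<double> &k1 = w.k1, &k2 = w.k2, &k3 = w.k3, &k4 = w.k4,
                      &k5 = w.k5, &k6 = w.k6, &k7 = w.k7, &yt = w.yt,
                      &ynew = w.ynew;
  double logcomp = 0.0;
  double s = 0.0;
  sse_rhs(p, y, k1.data());
  // initial step from the fastest derivative on unit scale; the error
  // control shrinks it if too optimistic
  double h;
  {
    double kmax = 1e-8;
    for (int i = 0; i < m; ++i) {
      double d = std::fabs(k1[i]);
      if (d > kmax) kmax = d;
    }
    h = std::min(t, 0.1 / kmax);
    if (h <= 0.0 || !std::isfinite(h)) h = t;
  }
  int nreject = 0;
  while (s < t * (1.0 - 1e-14)) {
    bool last = false;
    if (h >= t - s) {
      h = t - s;
      last = true;
    } else if (h < 1e-14 * t) {
      stop("SSE branch integration failed: step underflow");
    }
    for (int i = 0; i < m; ++i) yt[i] = y[i] + h * a21 * k1[i];
    sse_rhs(p, yt.data(), k2.data());
    for (int i = 0; i < m; ++i)
      yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    sse_rhs(p, yt.data(), k3.data());
    for (int i = 0; i < m; ++i)
      yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    sse_rhs(p, yt.data(), k4.data());
    for (int i = 0; i < m; ++i)
      yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                          a54 * k4[i]);
    sse_rhs(p, yt.data(), k5.data());
    for (int i = 0; i < m; ++i)
      yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                          a64 * k4[i] + a65 * k5[i]);
    sse_rhs(p, yt.data(), k6.data());
    for (int i = 0; i < m; ++i)
      ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                            b5 * k5[i] + b6 * k6[i]);
    sse_rhs(p, ynew.data(), k7.data());
    double errnorm = 0.0;
    for (int i = 0; i < m; ++i) {
      const double err = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                              e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
      const double sc = atol + rtol * std::max(std::fabs(y[i]),
                                               std::fabs(ynew[i]));
      const double q = err / sc;
      errnorm += q * q;
    }
    errnorm = std::sqrt(errnorm / m);
    if (!std::isfinite(errnorm)) errnorm = 1e10;
    if (errnorm <= 1.0) {
      s += h;
      if (last) s = t;
      for (int i = 0; i < m; ++i) y[i] = ynew[i];
      for (int i = 0; i < m; ++i) k1[i] = k7[i]; // FSAL
      // keep E in [0,1], D non-negative (clip integration jitter)
      for (int i = 0; i < n; ++i) {
        if (y[i] < 0.0) y[i] = 0.0;
        if (y[i] > 1.0) y[i] = 1.0;
        if (y[n + i] < 0.0) y[n + i] = 0.0;
      }
      double dmax = 0.0;
      for (int i = 0; i < n; ++i)
        if (y[n + i] > dmax) dmax = y[n + i];
      if (dmax > 0.0 && dmax < 1e-150) {
        for (int i = 0; i < n; ++i) y[n + i] /= dmax;
        logcomp += std::log(dmax);
        sse_rhs(p, y, k1.data());
      }
      nreject = 0;
    } else {
      if (++nreject > 200)
        stop("SSE branch integration failed: repeated step rejection");
    }
    double fac = 0.9 * std::pow(std::max(errnorm, 1e-10), -0.2);
    if (fac < 0.2) fac = 0.2;
    if (fac > 5.0) fac = 5.0;
    h *= fac;
  }
  return logcomp;
}

// [[Rcpp::export]]
List sse_branch_cpp(NumericVector E0, NumericVector D0, NumericVector lambda,
                    NumericVector mu, NumericMatrix Q, double t,
                    double rtol = 1e-8, double atol = 1e-10) {
  const int n = E0.size();
  if (D0.size() != n || lambda.size() != n || mu.size() != n ||
      Q.nrow() != n || Q.ncol() != n)
    stop("dimension mismatch in sse_branch_cpp");
  SSEPars p = {n, REAL(lambda), REAL(mu), REAL(Q)};
  SSEWork w(2 * n);
  std::vector<double> y(2 * n);
  for (int i = 0; i < n; ++i) {
    y[i] = E0[i];
    y[n + i] = D0[i];
  }
  double logcomp = integrate_branch(p, y.data(), t, rtol, atol, w);
  NumericVector E(n), D(n);
  for (int i = 0; i < n; ++i) {
    E[i] = y[i];
    D[i] = y[n + i];
  }
  return List::create(_["E"] = E, _["D"] = D, _["logcomp"] = logcomp);
}

// Full post-order pruning pass over a binary tree.
// edge: 2-column matrix (parent, child) in post-order; tips are 1..ntip,
// root is ntip + 1.  tipE/tipD: (ntip x n) initial conditions per tip.
// Returns root E, root D (lambda-weighted product of daughters, rescaled)
// and the accumulated log compensation.
// [[Rcpp::export]]
List sse_tree_cpp(IntegerMatrix edge, NumericVector edge_length, int ntip,
                  NumericMatrix tipE, NumericMatrix tipD,
                  NumericVector lambda, NumericVector mu, NumericMatrix Q,
                  double rtol = 1e-8, double atol = 1e-10) {
  const int n = lambda.size();
  const int nedge = edge.nrow();
  const int nnode = ntip + ntip; // upper bound on node ids (binary: 2*ntip-1)
  SSEPars p = {n, REAL(lambda), REAL(mu), REAL(Q)};
  // accumulated daughter products (D) and stored E per internal node
  std::vector<double> Dacc(static_cast<size_t>(nnode) * n, 1.0);
  std::vector<double> Estore(static_cast<size_t>(nnode) * n, 0.0);
  std::vector<int> nchild(nnode, 0);
  double logcomp = 0.0;
  SSEWork w(2 * n);
  std::vector<double> y(2 * n);
  for (int e = 0; e < nedge; ++e) {
    const int par = edge(e, 0) - 1, ch = edge(e, 1) - 1;
    if (ch < ntip) {
      for (int i = 0; i < n; ++i) {
        y[i] = tipE(ch, i);
        y[n + i] = tipD(ch, i);
      }
    } else {
      double dmax = 0.0;
      for (int i = 0; i < n; ++i) {
        y[i] = Estore[static_cast<size_t>(ch) * n + i];
        double d = lambda[i] * Dacc[static_cast<size_t>(ch) * n + i];
        y[n + i] = d;
        if (d > dmax) dmax = d;
      }
      if (dmax <= 0.0)
        return List::create(_["E"] = NumericVector(n),
                            _["D"] = NumericVector(n),
                            _["logcomp"] = R_NegInf);
      for (int i = 0; i < n; ++i) y[n + i] /= dmax;
      logcomp += std::log(dmax);
    }
    logcomp += integrate_branch(p, y.data(), edge_length[e], rtol, atol, w);
    for (int i = 0; i < n; ++i) {
      Dacc[static_cast<size_t>(par) * n + i] *= y[n + i];
      Estore[static_cast<size_t>(par) * n + i] = y[i];
    }
    nchild[par]++;
  }
  const int root = ntip; // 0-based index of node ntip+1
  NumericVector E(n), D(n);
  double dmax = 0.0;
  for (int i = 0; i < n; ++i) {
    E[i] = Estore[static_cast<size_t>(root) * n + i];
    D[i] = lambda[i] * Dacc[static_cast<size_t>(root) * n + i];
    if (D[i] > dmax) dmax = D[i];
  }
  if (dmax <= 0.0)
    return List::create(_["E"] = E, _["D"] = NumericVector(n),
                        _["logcomp"] = R_NegInf);
  for (int i = 0; i < n; ++i) D[i] = D[i] / dmax;
  logcomp += std::log(dmax);
  return List::create(_["E"] = E, _["D"] = D, _["logcomp"] = logcomp);
}
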