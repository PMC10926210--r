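#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Cox partial likelihood with delayed entry (left truncation) on the age
// scale. Rows must be sorted by `stop` ascending. Risk-set semantics:
// subject i is at risk at event time t iff start[i] < t <= stop[i]. Ties at
// an event time use the Breslow or Efron approximation.
//
// The sweep runs over stop times in decreasing order with two pointers: one
// adds subjects to the running sums S0, S1, S2 as t drops to their stop time,
// the other removes them once t drops to (or below) their start time.

struct CoxEval {
  double loglik;
  std::vector<double> grad;   // p
  std::vector<double> info;   // p x p (negative Hessian), row-major
};

static void cox_eval_core(const double* start, const double* stop,
                          const int* status, const double* X, int n, int p,
                          const int* by_start, const double* beta, bool efron,
                          CoxEval& out,
                          // optional per-event-time detail (descending order)
                          std::vector<double>* d_time = nullptr,
                          std::vector<double>* d_d = nullptr,
                          std::vector<double>* d_S0 = nullptr,
                          std::vector<double>* d_xbar = nullptr,
                          std::vector<double>* d_xsum = nullptr) {
  std::vector<double> r(n), eta(n);
  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) e += X[i + j * n] * beta[j];
    eta[i] = e;
    r[i] = std::exp(e);
  }
  out.loglik = 0.0;
  out.grad.assign(p, 0.0);
  out.info.assign(p * p, 0.0);

  double S0 = 0.0;
  std::vector<double> S1(p, 0.0), S2(p * p, 0.0);
  std::vector<double> S1t(p), S2t(p * p), xsum(p);

  int add = n - 1, rm = 0, i = n - 1;
  while (i >= 0) {
    const double t = stop[i];
    while (add >= 0 && stop[add] >= t) {
      const double ri = r[add];
      S0 += ri;
      for (int j = 0; j < p; ++j) {
        const double xr = X[add + j * n] * ri;
        S1[j] += xr;
        for (int k = j; k < p; ++k) S2[j * p + k] += xr * X[add + k * n];
      }
      --add;
    }
    while (rm < n && start[by_start[rm]] >= t) {
      const int a = by_start[rm];
      const double ri = r[a];
      S0 -= ri;
      for (int j = 0; j < p; ++j) {
        const double xr = X[a + j * n] * ri;
        S1[j] -= xr;
        for (int k = j; k < p; ++k) S2[j * p + k] -= xr * X[a + k * n];
      }
      ++rm;
    }
    int d = 0;
    double sum_eta = 0.0, S0t = 0.0;
    std::fill(S1t.begin(), S1t.end(), 0.0);
    std::fill(S2t.begin(), S2t.end(), 0.0);
    std::fill(xsum.begin(), xsum.end(), 0.0);
    int j = i;
    while (j >= 0 && stop[j] == t) {
      if (status[j] == 1) {
        ++d;
        sum_eta += eta[j];
        const double rj = r[j];
        S0t += rj;
        for (int a = 0; a < p; ++a) {
          xsum[a] += X[j + a * n];
          const double xr = X[j + a * n] * rj;
          S1t[a] += xr;
          for (int b = a; b < p; ++b) S2t[a * p + b] += xr * X[j + b * n];
        }
      }
      --j;
    }
    if (d > 0) {
      if (!efron || d == 1) {
        out.loglik += sum_eta - d * std::log(S0);
        for (int a = 0; a < p; ++a) {
          const double m = S1[a] / S0;
          out.grad[a] += xsum[a] - d * m;
          for (int b = a; b < p; ++b)
            out.info[a * p + b] += d * (S2[a * p + b] / S0 - m * S1[b] / S0);
        }
      } else {
        out.loglik += sum_eta;
        for (int l = 0; l < d; ++l) {
          const double f = (double)l / d;
          const double S0l = S0 - f * S0t;
          out.loglik -= std::log(S0l);
          for (int a = 0; a < p; ++a) {
            const double m = (S1[a] - f * S1t[a]) / S0l;
            out.grad[a] += xsum[a] / d - m;
            for (int b = a; b < p; ++b) {
              const double mb = (S1[b] - f * S1t[b]) / S0l;
              out.info[a * p + b] +=
                (S2[a * p + b] - f * S2t[a * p + b]) / S0l - m * mb;
            }
          }
        }
      }
      if (d_time) {
        d_time->push_back(t);
        d_d->push_back((double)d);
        d_S0->push_back(S0);
        for (int a = 0; a < p; ++a) {
          d_xbar->push_back(S1[a] / S0);
          d_xsum->push_back(xsum[a]);
        }
      }
    }
    i = j;
  }
  // mirror the upper triangle
  for (int a = 0; a < p; ++a)
    for (int b = a + 1; b < p; ++b) out.info[b * p + a] = out.info[a * p + b];
}

static std::vector<int> start_order_desc(const NumericVector& start) {
  const int n = start.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return start[a] > start[b]; });
  return idx;
}

// Solve A x = b for symmetric positive definite A (p small), Cholesky.
// Returns false if not positive definite.
static bool chol_solve(std::vector<double> A, const std::vector<double>& b,
                       std::vector<double>& x, int p) {
  std::vector<double> L(p * p, 0.0);
  for (int j = 0; j < p; ++j) {
    double s = A[j * p + j];
    for (int k = 0; k < j; ++k) s -= L[j * p + k] * L[j * p + k];
    if (s <= 0) return false;
    L[j * p + j] = std::sqrt(s);
    for (int i = j + 1; i < p; ++i) {
      double v = A[i * p + j];
      for (int k = 0; k < j; ++k) v -= L[i * p + k] * L[j * p + k];
      L[i * p + j] = v / L[j * p + j];
    }
  }
  x = b;
  for (int i = 0; i < p; ++i) {
    for (int k = 0; k < i; ++k) x[i] -= L[i * p + k] * x[k];
    x[i] /= L[i * p + i];
  }
  for (int i = p - 1; i >= 0; --i) {
    for (int k = i + 1; k < p; ++k) x[i] -= L[k * p + i] * x[k];
    x[i] /= L[i * p + i];
  }
  return true;
}

// Newton-Raphson maximizer with step-halving; `beta_bound` flags a suspected
// monotone likelihood (coefficient running away) as non-convergence.
// [[Rcpp::export]]
List cox_fit_cpp(NumericVector start, NumericVector stop, IntegerVector status,
                 NumericMatrix X, bool efron, double tol, int max_iter,
                 double beta_bound) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<int> by_start = start_order_desc(start);
  std::vector<double> beta(p, 0.0);

  CoxEval ev;
  cox_eval_core(REAL(start), REAL(stop), INTEGER(status), REAL(X), n, p,
                by_start.data(), beta.data(), efron, ev);
  double nll = -ev.loglik;
  bool converged = false, monotone = false;
  int iter = 0;
  std::vector<double> delta(p), cand(p);
  CoxEval ev_new;
  while (iter < max_iter) {
    ++iter;
    std::vector<double> A = ev.info;
    if (!chol_solve(A, ev.grad, delta, p)) {
      for (int j = 0; j < p; ++j) A[j * p + j] += 1e-8;
      if (!chol_solve(A, ev.grad, delta, p)) break;
    }
    double step = 1.0;
    bool stalled = false;
    for (;;) {
      for (int j = 0; j < p; ++j) cand[j] = beta[j] + step * delta[j];
      cox_eval_core(REAL(start), REAL(stop), INTEGER(status), REAL(X), n, p,
                    by_start.data(), cand.data(), efron, ev_new);
      if (std::isfinite(ev_new.loglik) && -ev_new.loglik <= nll + 1e-12) break;
      step /= 2;
      if (step < 1e-10) { cand = beta; ev_new = ev; stalled = true; break; }
    }
    double dmax = 0.0;
    for (int j = 0; j < p; ++j)
      dmax = std::max(dmax, std::abs(cand[j] - beta[j]));
    beta = cand;
    ev = ev_new;
    nll = -ev.loglik;
    double gmax = 0.0, bmax = 0.0;
    for (int j = 0; j < p; ++j) {
      gmax = std::max(gmax, std::abs(ev.grad[j]));
      bmax = std::max(bmax, std::abs(beta[j]));
    }
    if (gmax <= tol) { converged = true; break; }
    if (stalled || dmax <= 1e-9 * (1.0 + bmax)) {
      // at floating-point resolution of the optimum: the objective cannot
      // improve and the Newton increment is negligible. Accept if the
      // gradient is tiny on the event-count scale (the gradient's own noise
      // floor can sit above `tol` for large samples).
      converged = gmax <= 1e-4;
      break;
    }
    if (bmax > beta_bound) { monotone = true; break; }
  }
  NumericVector bout(p), gout(p);
  NumericMatrix iout(p, p);
  for (int a = 0; a < p; ++a) {
    bout[a] = beta[a];
    gout[a] = ev.grad[a];
    for (int b = 0; b < p; ++b) iout(a, b) = ev.info[a * p + b];
  }
  return List::create(_["coef"] = bout, _["loglik"] = ev.loglik,
                      _["grad"] = gout, _["info"] = iout,
                      _["iter"] = iter, _["converged"] = converged,
                      _["monotone"] = monotone);
}

// Single evaluation at `beta`, optionally with the per-event-time summaries
// (ascending in time) needed for Schoenfeld and score residuals.
// [[Rcpp::export]]
List cox_eval_cpp(NumericVector start, NumericVector stop, IntegerVector status,
                  NumericMatrix X, NumericVector beta, bool efron,
                  bool detail) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<int> by_start = start_order_desc(start);
  CoxEval ev;
  std::vector<double> d_time, d_d, d_S0, d_xbar, d_xsum;
  std::vector<double> b(beta.begin(), beta.end());
  cox_eval_core(REAL(start), REAL(stop), INTEGER(status), REAL(X), n, p,
                by_start.data(), b.data(), efron, ev,
                detail ? &d_time : nullptr, detail ? &d_d : nullptr,
                detail ? &d_S0 : nullptr, detail ? &d_xbar : nullptr,
                detail ? &d_xsum : nullptr);
  NumericVector g(p);
  NumericMatrix H(p, p);
  for (int a = 0; a < p; ++a) {
    g[a] = ev.grad[a];
    for (int b2 = 0; b2 < p; ++b2) H(a, b2) = ev.info[a * p + b2];
  }
  List out = List::create(_["loglik"] = ev.loglik, _["grad"] = g,
                          _["info"] = H);
  if (detail) {
    const int K = d_time.size();
    NumericVector et(K), dd(K), s0(K);
    NumericMatrix xbar(K, p), xs(K, p);
    for (int k = 0; k < K; ++k) {  // stored descending; reverse to ascending
      const int src = K - 1 - k;
      et[k] = d_time[src];
      dd[k] = d_d[src];
      s0[k] = d_S0[src];
      for (int a = 0; a < p; ++a) {
        xbar(k, a) = d_xbar[src * p + a];
        xs(k, a) = d_xsum[src * p + a];
      }
    }
    out["etime"] = et;
    out["nevent"] = dd;
    out["S0"] = s0;
    out["xbar"] = xbar;
    out["xsum"] = xs;
  }
  return out;
}
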