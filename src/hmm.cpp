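// Log-space dynamic programs for a first-order HMM with silent begin/end
// states. State 0 is begin, state m-1 is end, states 1..m-2 emit.
// All matrices hold log-probabilities; structural zeros are -Inf.
// obs is 1-based (1..4 for A,C,G,T).

#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

static const double NEG_INF = R_NegInf;

// log(sum(exp(v))) over the finite entries of a buffer
static inline double log_sum_exp(const std::vector<double>& v) {
  double mx = NEG_INF;
  for (double x : v) if (x > mx) mx = x;
  if (mx == NEG_INF) return NEG_INF;
  double s = 0.0;
  for (double x : v) if (x > NEG_INF) s += std::exp(x - mx);
  return mx + std::log(s);
}

static void forward_fill(const NumericMatrix& logA, const NumericMatrix& logE,
                         const IntegerVector& obs, NumericMatrix& f) {
  const int m = logA.nrow(), n = obs.size();
  std::vector<double> buf;
  buf.reserve(m);
  for (int k = 1; k < m - 1; ++k) {
    double a = logA(0, k), e = logE(k, obs[0] - 1);
    f(0, k) = (a == NEG_INF || e == NEG_INF) ? NEG_INF : a + e;
  }
  for (int i = 1; i < n; ++i) {
    for (int k = 1; k < m - 1; ++k) {
      double e = logE(k, obs[i] - 1);
      if (e == NEG_INF) { f(i, k) = NEG_INF; continue; }
      buf.clear();
      for (int j = 1; j < m - 1; ++j) {
        double a = logA(j, k), fp = f(i - 1, j);
        if (a > NEG_INF && fp > NEG_INF) buf.push_back(fp + a);
      }
      double s = log_sum_exp(buf);
      f(i, k) = (s == NEG_INF) ? NEG_INF : s + e;
    }
  }
}

static double forward_terminate(const NumericMatrix& logA, const NumericMatrix& f,
                                int n) {
  const int m = logA.nrow();
  std::vector<double> buf;
  for (int k = 1; k < m - 1; ++k) {
    double a = logA(k, m - 1), fp = f(n - 1, k);
    if (a > NEG_INF && fp > NEG_INF) buf.push_back(fp + a);
  }
  return log_sum_exp(buf);
}

static void backward_fill(const NumericMatrix& logA, const NumericMatrix& logE,
                          const IntegerVector& obs, NumericMatrix& b) {
  const int m = logA.nrow(), n = obs.size();
  std::vector<double> buf;
  for (int k = 1; k < m - 1; ++k) b(n - 1, k) = logA(k, m - 1);
  for (int i = n - 2; i >= 0; --i) {
    for (int k = 1; k < m - 1; ++k) {
      buf.clear();
      for (int j = 1; j < m - 1; ++j) {
        double a = logA(k, j), e = logE(j, obs[i + 1] - 1), bn = b(i + 1, j);
        if (a > NEG_INF && e > NEG_INF && bn > NEG_INF) buf.push_back(a + e + bn);
      }
      b(i, k) = log_sum_exp(buf);
    }
  }
}

// [[Rcpp::export]]
List hmm_forward_cpp(NumericMatrix logA, NumericMatrix logE, IntegerVector obs) {
  const int m = logA.nrow(), n = obs.size();
  NumericMatrix f(n, m);
  std::fill(f.begin(), f.end(), NEG_INF);
  forward_fill(logA, logE, obs, f);
  return List::create(_["logf"] = f,
                      _["loglik"] = forward_terminate(logA, f, n));
}

// [[Rcpp::export]]
List hmm_backward_cpp(NumericMatrix logA, NumericMatrix logE, IntegerVector obs) {
  const int m = logA.nrow(), n = obs.size();
  NumericMatrix b(n, m);
  std::fill(b.begin(), b.end(), NEG_INF);
  backward_fill(logA, logE, obs, b);
  std::vector<double> buf;
  for (int k = 1; k < m - 1; ++k) {
    double a = logA(0, k), e = logE(k, obs[0] - 1), bn = b(0, k);
    if (a > NEG_INF && e > NEG_INF && bn > NEG_INF) buf.push_back(a + e + bn);
  }
  return List::create(_["logb"] = b, _["loglik"] = log_sum_exp(buf));
}

// Most probable state path; ties broken toward the lowest state index
// (strict ">" while scanning predecessors in ascending order).
// [[Rcpp::export]]
List hmm_viterbi_cpp(NumericMatrix logA, NumericMatrix logE, IntegerVector obs) {
  const int m = logA.nrow(), n = obs.size();
  NumericMatrix v(n, m);
  IntegerMatrix ptr(n, m);
  std::fill(v.begin(), v.end(), NEG_INF);
  std::fill(ptr.begin(), ptr.end(), -1);
  for (int k = 1; k < m - 1; ++k) {
    double a = logA(0, k), e = logE(k, obs[0] - 1);
    if (a > NEG_INF && e > NEG_INF) v(0, k) = a + e;
  }
  for (int i = 1; i < n; ++i) {
    for (int k = 1; k < m - 1; ++k) {
      double e = logE(k, obs[i] - 1);
      if (e == NEG_INF) continue;
      double best = NEG_INF;
      int arg = -1;
      for (int j = 1; j < m - 1; ++j) {
        double a = logA(j, k), vp = v(i - 1, j);
        if (a == NEG_INF || vp == NEG_INF) continue;
        double cand = vp + a;
        if (cand > best) { best = cand; arg = j; }
      }
      if (arg >= 0) { v(i, k) = best + e; ptr(i, k) = arg; }
    }
  }
  double best = NEG_INF;
  int last = -1;
  for (int k = 1; k < m - 1; ++k) {
    double a = logA(k, m - 1), vp = v(n - 1, k);
    if (a == NEG_INF || vp == NEG_INF) continue;
    double cand = vp + a;
    if (cand > best) { best = cand; last = k; }
  }
  if (last < 0)
    return List::create(_["path"] = IntegerVector(0), _["logprob"] = NEG_INF);
  IntegerVector path(n);
  path[n - 1] = last;
  for (int i = n - 1; i > 0; --i) path[i - 1] = ptr(i, path[i]);
  for (int i = 0; i < n; ++i) path[i] += 1;  // back to R's 1-based indexing
  return List::create(_["path"] = path, _["logprob"] = best);
}

// Expected transition and emission counts for one sequence (E-step of
// Baum-Welch), plus its log-likelihood under the current parameters.
// [[Rcpp::export]]
List hmm_expected_counts_cpp(NumericMatrix logA, NumericMatrix logE,
                             IntegerVector obs) {
  const int m = logA.nrow(), n = obs.size();
  NumericMatrix A(m, m), E(m, logE.ncol());
  NumericMatrix f(n, m), b(n, m);
  std::fill(f.begin(), f.end(), NEG_INF);
  std::fill(b.begin(), b.end(), NEG_INF);
  forward_fill(logA, logE, obs, f);
  const double ll = forward_terminate(logA, f, n);
  if (ll == NEG_INF)
    return List::create(_["trans"] = A, _["emis"] = E, _["loglik"] = ll);
  backward_fill(logA, logE, obs, b);

  for (int k = 1; k < m - 1; ++k) {
    // begin -> k and k -> end
    double a0 = logA(0, k), e0 = logE(k, obs[0] - 1);
    if (a0 > NEG_INF && e0 > NEG_INF && b(0, k) > NEG_INF)
      A(0, k) += std::exp(a0 + e0 + b(0, k) - ll);
    double ae = logA(k, m - 1);
    if (ae > NEG_INF && f(n - 1, k) > NEG_INF)
      A(k, m - 1) += std::exp(f(n - 1, k) + ae - ll);
    // state occupancy -> emission counts
    for (int i = 0; i < n; ++i) {
      if (f(i, k) > NEG_INF && b(i, k) > NEG_INF)
        E(k, obs[i] - 1) += std::exp(f(i, k) + b(i, k) - ll);
    }
  }
  for (int j = 1; j < m - 1; ++j) {
    for (int k = 1; k < m - 1; ++k) {
      double a = logA(j, k);
      if (a == NEG_INF) continue;
      double acc = 0.0;
      for (int i = 0; i + 1 < n; ++i) {
        double e = logE(k, obs[i + 1] - 1);
        if (f(i, j) > NEG_INF && e > NEG_INF && b(i + 1, k) > NEG_INF)
          acc += std::exp(f(i, j) + a + e + b(i + 1, k) - ll);
      }
      A(j, k) += acc;
    }
  }
  return List::create(_["trans"] = A, _["emis"] = E, _["loglik"] = ll);
}
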