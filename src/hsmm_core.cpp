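// Explicit-duration HSMM recursions (log space).
//
// Conventions shared with the R layer:
//  - E:      K x T matrix of per-state log emission densities log N(y_t; mu_k, Sigma_k)
//  - logpmf: K x D matrix, log dwell pmf on durations 1..D (renormalized truncation)
//  - logS:   K x D matrix, log survival  S_k(d) = P(dwell >= d)
//  - logA:   K x K log transition matrix with -Inf diagonal (no self-transitions)
//  - logpi:  length-K log initial state probabilities
//  - The first dwell starts at t = 1; the final dwell is right-censored at T
//    (survival term), so path probabilities sum to one and match the sampler,
//    which truncates the last drawn dwell at the end of the scan.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse(const std::vector<double> &v) {
  double m = NEG_INF;
  for (double x : v) if (x > m) m = x;
  if (m == NEG_INF) return NEG_INF;
  double s = 0.0;
  for (double x : v) s += std::exp(x - m);
  return m + std::log(s);
}

// Cumulative emission log-likelihoods: C[k][t] = sum_{s<=t} E(k,s), C[k][0] = 0.
static std::vector<double> cum_emissions(const NumericMatrix &E) {
  int K = E.nrow(), T = E.ncol();
  std::vector<double> C((size_t)K * (T + 1));
  for (int k = 0; k < K; ++k) {
    C[(size_t)k * (T + 1)] = 0.0;
    for (int t = 1; t <= T; ++t)
      C[(size_t)k * (T + 1) + t] = C[(size_t)k * (T + 1) + t - 1] + E(k, t - 1);
  }
  return C;
}

// ent(k, t-1): log prob of data up to t-1 and a segment of state k starting at t.
// alpha(k, t-1): log prob of data up to t with a segment of state k ending at t.
static void forward_pass(const NumericMatrix &E, const NumericMatrix &logpmf,
                         const NumericMatrix &logS, const NumericMatrix &logA,
                         const NumericVector &logpi,
                         const std::vector<double> &C,
                         NumericMatrix &ent, NumericMatrix &alpha,
                         double &loglik) {
  int K = E.nrow(), T = E.ncol(), D = logpmf.ncol();
  auto B = [&](int k, int t1, int t2) {  // inclusive, 1-based
    return C[(size_t)k * (T + 1) + t2] - C[(size_t)k * (T + 1) + t1 - 1];
  };
  std::vector<double> buf;
  buf.reserve(std::max(K, D));
  for (int t = 1; t <= T; ++t) {
    for (int k = 0; k < K; ++k) {
      double e;
      if (t == 1) {
        e = logpi[k];
      } else {
        buf.clear();
        for (int j = 0; j < K; ++j) {
          if (j == k || logA(j, k) == NEG_INF) continue;
          double a = alpha(j, t - 2);
          if (a == NEG_INF) continue;
          buf.push_back(a + logA(j, k));
        }
        e = lse(buf);
      }
      ent(k, t - 1) = e;
    }
    for (int k = 0; k < K; ++k) {
      buf.clear();
      int dmax = std::min(t, D);
      for (int d = 1; d <= dmax; ++d) {
        double en = ent(k, t - d);
        if (en == NEG_INF || logpmf(k, d - 1) == NEG_INF) continue;
        buf.push_back(en + B(k, t - d + 1, t) + logpmf(k, d - 1));
      }
      alpha(k, t - 1) = lse(buf);
    }
  }
  buf.clear();
  for (int k = 0; k < K; ++k) {
    int dmax = std::min(T, D);
    for (int d = 1; d <= dmax; ++d) {
      double en = ent(k, T - d);
      if (en == NEG_INF || logS(k, d - 1) == NEG_INF) continue;
      buf.push_back(en + B(k, T - d + 1, T) + logS(k, d - 1));
    }
  }
  loglik = lse(buf);
}

// [[Rcpp::export]]
double hsmm_forward_cpp(NumericMatrix E, NumericMatrix logpmf,
                        NumericMatrix logS, NumericMatrix logA,
                        NumericVector logpi) {
  int K = E.nrow(), T = E.ncol();
  NumericMatrix ent(K, T), alpha(K, T);
  std::vector<double> C = cum_emissions(E);
  double loglik;
  forward_pass(E, logpmf, logS, logA, logpi, C, ent, alpha, loglik);
  return loglik;
}

// Forward-backward with expected sufficient statistics.
// Returns gamma (K x T state occupation posteriors), expected dwell counts for
// uncensored segments (K x D), censored-tail dwell mass (K x D), expected
// transition counts (K x K), posterior of the initial segment state (K).
// [[Rcpp::export]]
List hsmm_fb_cpp(NumericMatrix E, NumericMatrix logpmf, NumericMatrix logS,
                 NumericMatrix logA, NumericVector logpi) {
  int K = E.nrow(), T = E.ncol(), D = logpmf.ncol();
  NumericMatrix ent(K, T), alpha(K, T);
  std::vector<double> C = cum_emissions(E);
  auto B = [&](int k, int t1, int t2) {
    return C[(size_t)k * (T + 1) + t2] - C[(size_t)k * (T + 1) + t1 - 1];
  };
  double loglik;
  forward_pass(E, logpmf, logS, logA, logpi, C, ent, alpha, loglik);
  if (!R_finite(loglik))
    stop("non-finite HSMM log-likelihood in forward pass");

  // Backward: beta(k, t-1) = log p(y_t..T | segment of state k starts at t);
  // h(k, t-1) = lse_{j != k} logA(k,j) + beta(j, t-1).
  NumericMatrix beta(K, T), h(K, T);
  std::vector<double> buf;
  buf.reserve(std::max(K, D));
  for (int t = T; t >= 1; --t) {
    for (int k = 0; k < K; ++k) {
      buf.clear();
      int dmax = std::min(D, T - t + 1);
      for (int d = 1; d <= dmax; ++d) {
        int end = t + d - 1;
        if (end < T) {
          if (logpmf(k, d - 1) == NEG_INF) continue;
          double hh = h(k, end);  // column index end == time end+1
          if (hh == NEG_INF) continue;
          buf.push_back(B(k, t, end) + logpmf(k, d - 1) + hh);
        } else {
          if (logS(k, d - 1) == NEG_INF) continue;
          buf.push_back(B(k, t, T) + logS(k, d - 1));
        }
      }
      beta(k, t - 1) = lse(buf);
    }
    for (int k = 0; k < K; ++k) {
      buf.clear();
      for (int j = 0; j < K; ++j) {
        if (j == k || logA(k, j) == NEG_INF) continue;
        double b = beta(j, t - 1);
        if (b == NEG_INF) continue;
        buf.push_back(logA(k, j) + b);
      }
      h(k, t - 1) = lse(buf);
    }
  }

  // Segment posteriors xi(t0, k, d), accumulated into the statistics.
  NumericMatrix occdiff(K, T + 1), dwell(K, D), dwell_cens(K, D), trans(K, K);
  NumericVector initpost(K);
  for (int t0 = 1; t0 <= T; ++t0) {
    for (int k = 0; k < K; ++k) {
      double en = ent(k, t0 - 1);
      if (en == NEG_INF) continue;
      int dmax = std::min(D, T - t0 + 1);
      for (int d = 1; d <= dmax; ++d) {
        int end = t0 + d - 1;
        double lx;
        if (end < T) {
          if (logpmf(k, d - 1) == NEG_INF || h(k, end) == NEG_INF) continue;
          lx = en + B(k, t0, end) + logpmf(k, d - 1) + h(k, end);
        } else {
          if (logS(k, d - 1) == NEG_INF) continue;
          lx = en + B(k, t0, T) + logS(k, d - 1);
        }
        double x = std::exp(lx - loglik);
        if (!(x > 0)) continue;
        occdiff(k, t0 - 1) += x;
        occdiff(k, t0 - 1 + d) -= x;
        if (end < T) dwell(k, d - 1) += x; else dwell_cens(k, d - 1) += x;
        if (t0 == 1) initpost[k] += x;
      }
    }
  }
  NumericMatrix gamma(K, T);
  for (int k = 0; k < K; ++k) {
    double acc = 0.0;
    for (int t = 0; t < T; ++t) {
      acc += occdiff(k, t);
      gamma(k, t) = acc;
    }
  }
  for (int t = 2; t <= T; ++t)
    for (int k = 0; k < K; ++k) {
      double a = alpha(k, t - 2);
      if (a == NEG_INF) continue;
      for (int j = 0; j < K; ++j) {
        if (j == k || logA(k, j) == NEG_INF) continue;
        double b = beta(j, t - 1);
        if (b == NEG_INF) continue;
        trans(k, j) += std::exp(a + logA(k, j) + b - loglik);
      }
    }

  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["dwell_counts"] = dwell,
                      _["dwell_censored"] = dwell_cens,
                      _["trans_counts"] = trans, _["init_post"] = initpost);
}

// Duration-aware Viterbi. Ties broken toward the lower state index, then the
// shorter dwell (first strict improvement wins, loops ordered accordingly).
// [[Rcpp::export]]
List hsmm_viterbi_cpp(NumericMatrix E, NumericMatrix logpmf, NumericMatrix logS,
                      NumericMatrix logA, NumericVector logpi) {
  int K = E.nrow(), T = E.ncol(), D = logpmf.ncol();
  std::vector<double> C = cum_emissions(E);
  auto B = [&](int k, int t1, int t2) {
    return C[(size_t)k * (T + 1) + t2] - C[(size_t)k * (T + 1) + t1 - 1];
  };
  NumericMatrix entv(K, T), alphav(K, T);
  IntegerMatrix argj(K, T), argd(K, T);
  for (int t = 1; t <= T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = NEG_INF;
      int bj = -1;
      if (t == 1) {
        best = logpi[k];
      } else {
        for (int j = 0; j < K; ++j) {
          if (j == k || logA(j, k) == NEG_INF) continue;
          double v = alphav(j, t - 2);
          if (v == NEG_INF) continue;
          v += logA(j, k);
          if (v > best) { best = v; bj = j; }
        }
      }
      entv(k, t - 1) = best;
      argj(k, t - 1) = bj;
    }
    for (int k = 0; k < K; ++k) {
      double best = NEG_INF;
      int bd = -1;
      int dmax = std::min(t, D);
      for (int d = 1; d <= dmax; ++d) {
        double en = entv(k, t - d);
        if (en == NEG_INF || logpmf(k, d - 1) == NEG_INF) continue;
        double v = en + B(k, t - d + 1, t) + logpmf(k, d - 1);
        if (v > best) { best = v; bd = d; }
      }
      alphav(k, t - 1) = best;
      argd(k, t - 1) = bd;
    }
  }
  double best = NEG_INF;
  int bk = -1, bd = -1;
  for (int k = 0; k < K; ++k) {
    int dmax = std::min(T, D);
    for (int d = 1; d <= dmax; ++d) {
      double en = entv(k, T - d);
      if (en == NEG_INF || logS(k, d - 1) == NEG_INF) continue;
      double v = en + B(k, T - d + 1, T) + logS(k, d - 1);
      if (v > best) { best = v; bk = k; bd = d; }
    }
  }
  if (bk < 0) stop("no feasible state path (all paths have zero probability)");

  IntegerVector labels(T);
  int t0 = T - bd + 1, k = bk;
  for (int t = t0; t <= T; ++t) labels[t - 1] = k;
  while (t0 > 1) {
    int j = argj(k, t0 - 1);
    int tend = t0 - 1;
    int d2 = argd(j, tend - 1);
    for (int t = tend - d2 + 1; t <= tend; ++t) labels[t - 1] = j;
    t0 = tend - d2 + 1;
    k = j;
  }
  return List::create(_["labels"] = labels, _["log_joint"] = best);
}
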