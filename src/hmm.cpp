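#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Log-domain HMM recursions. Conventions shared with the R layer:
//  - logB: T x N matrix of per-frame, per-state emission log-densities
//  - logA: N x N log transition matrix (-Inf encodes a masked transition)
//  - all indices returned to R are 1-based
// Ties in any argmax break toward the lowest state index (strict >).

static inline double logsumexp_row(const std::vector<double>& v) {
  double m = R_NegInf;
  for (double x : v) if (x > m) m = x;
  if (!R_finite(m)) return R_NegInf;
  double s = 0.0;
  for (double x : v) s += std::exp(x - m);
  return m + std::log(s);
}

// Forward-backward with sufficient-statistic accumulation for Baum-Welch.
// Returns log P(O|lambda), posterior state probabilities gamma (T x N) and
// the expected transition counts xi_sum (N x N, masked entries are 0).
// [[Rcpp::export]]
List hmm_forward_backward(NumericMatrix logB, NumericMatrix logA,
                          NumericVector logpi) {
  const int T = logB.nrow(), N = logB.ncol();
  NumericMatrix logalpha(T, N), logbeta(T, N);
  std::vector<double> acc(N);

  for (int i = 0; i < N; ++i) logalpha(0, i) = logpi[i] + logB(0, i);
  for (int t = 1; t < T; ++t) {
    for (int i = 0; i < N; ++i) {
      for (int j = 0; j < N; ++j) acc[j] = logalpha(t - 1, j) + logA(j, i);
      logalpha(t, i) = logsumexp_row(acc) + logB(t, i);
    }
  }
  for (int i = 0; i < N; ++i) acc[i] = logalpha(T - 1, i);
  const double loglik = logsumexp_row(acc);

  for (int i = 0; i < N; ++i) logbeta(T - 1, i) = 0.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < N; ++i) {
      for (int j = 0; j < N; ++j)
        acc[j] = logA(i, j) + logB(t + 1, j) + logbeta(t + 1, j);
      logbeta(t, i) = logsumexp_row(acc);
    }
  }

  NumericMatrix gamma(T, N);
  for (int t = 0; t < T; ++t)
    for (int i = 0; i < N; ++i) {
      double lg = logalpha(t, i) + logbeta(t, i) - loglik;
      gamma(t, i) = R_finite(lg) ? std::exp(lg) : 0.0;
    }

  NumericMatrix xi_sum(N, N);
  for (int t = 0; t + 1 < T; ++t)
    for (int i = 0; i < N; ++i) {
      if (!R_finite(logalpha(t, i))) continue;
      for (int j = 0; j < N; ++j) {
        if (!R_finite(logA(i, j))) continue;
        double lx = logalpha(t, i) + logA(i, j) + logB(t + 1, j) +
                    logbeta(t + 1, j) - loglik;
        if (R_finite(lx)) xi_sum(i, j) += std::exp(lx);
      }
    }

  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["xi_sum"] = xi_sum);
}

// Max-product (Viterbi) recursion over one window. init_logdelta is the
// already-formed delta_1 vector (initial distribution or the marginalized
// hand-off from the previous window, emission of frame 1 included), so the
// same kernel serves classic full-sequence decoding and windowed decoding.
// Backtracking starts at the argmax terminal state; the first frame carries
// no backpointer (psi_1 = 0).
// [[Rcpp::export]]
List hmm_viterbi(NumericMatrix logB, NumericMatrix logA,
                 NumericVector init_logdelta) {
  const int T = logB.nrow(), N = logB.ncol();
  NumericMatrix logdelta(T, N);
  IntegerMatrix psi(T, N);

  for (int i = 0; i < N; ++i) {
    logdelta(0, i) = init_logdelta[i];
    psi(0, i) = 0;
  }
  for (int t = 1; t < T; ++t) {
    for (int i = 0; i < N; ++i) {
      double best = R_NegInf;
      int arg = 0;
      for (int j = 0; j < N; ++j) {
        double cand = logdelta(t - 1, j) + logA(j, i);
        if (cand > best) { best = cand; arg = j; }
      }
      logdelta(t, i) = best + logB(t, i);
      psi(t, i) = arg + 1;
    }
  }

  double best = R_NegInf;
  int arg = 0;
  for (int i = 0; i < N; ++i)
    if (logdelta(T - 1, i) > best) { best = logdelta(T - 1, i); arg = i; }

  IntegerVector path(T);
  path[T - 1] = arg + 1;
  for (int t = T - 1; t >= 1; --t) path[t - 1] = psi(t, path[t] - 1);

  return List::create(_["path"] = path,
                      _["logdelta_T"] = NumericVector(logdelta(T - 1, _)),
                      _["logprob"] = best);
}
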