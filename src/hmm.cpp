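#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Scaled-forward HMM log-likelihood with per-chromosome resets.
// logE: S x N matrix of log emission probabilities
// M:    S x S row-stochastic transition matrix (probability scale)
// pi:   length-S initial (steady-state) distribution, used at the start of
//       every chromosome block
// chromStart: 1-based indices of the first window of each chromosome
// [[Rcpp::export]]
double hmm_forward_cpp(const NumericMatrix& logE, const NumericMatrix& M,
                       const NumericVector& pi,
                       const IntegerVector& chromStart) {
  const int S = logE.nrow(), N = logE.ncol();
  std::vector<double> alpha(S), tmp(S), e(S);
  std::vector<bool> isStart(N + 1, false);
  for (int b = 0; b < chromStart.size(); ++b) isStart[chromStart[b]] = true;
  double loglik = 0.0;
  for (int i = 0; i < N; ++i) {
    // scale emissions for window i
    double emax = -std::numeric_limits<double>::infinity();
    for (int s = 0; s < S; ++s) emax = std::max(emax, logE(s, i));
    if (!std::isfinite(emax)) return -std::numeric_limits<double>::infinity();
    for (int s = 0; s < S; ++s) e[s] = std::exp(logE(s, i) - emax);
    if (isStart[i + 1]) {
      for (int s = 0; s < S; ++s) alpha[s] = pi[s] * e[s];
    } else {
      for (int s = 0; s < S; ++s) tmp[s] = 0.0;
      for (int r = 0; r < S; ++r) {
        const double a = alpha[r];
        if (a == 0.0) continue;
        for (int s = 0; s < S; ++s) tmp[s] += a * M(r, s);
      }
      for (int s = 0; s < S; ++s) alpha[s] = tmp[s] * e[s];
    }
    double norm = 0.0;
    for (int s = 0; s < S; ++s) norm += alpha[s];
    if (norm <= 0.0 || !std::isfinite(norm))
      return -std::numeric_limits<double>::infinity();
    for (int s = 0; s < S; ++s) alpha[s] /= norm;
    loglik += std::log(norm) + emax;
  }
  return loglik;
}

// Viterbi decoding with per-chromosome resets; ties broken toward the
// smaller state index. Returns 1-based state indices.
// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(const NumericMatrix& logE,
                              const NumericMatrix& M,
                              const NumericVector& pi,
                              const IntegerVector& chromStart) {
  const int S = logE.nrow(), N = logE.ncol();
  NumericMatrix logM(S, S);
  for (int r = 0; r < S; ++r)
    for (int s = 0; s < S; ++s)
      logM(r, s) = M(r, s) > 0 ? std::log(M(r, s))
                               : -std::numeric_limits<double>::infinity();
  NumericVector logPi(S);
  for (int s = 0; s < S; ++s)
    logPi[s] = pi[s] > 0 ? std::log(pi[s])
                         : -std::numeric_limits<double>::infinity();
  std::vector<bool> isStart(N + 1, false);
  for (int b = 0; b < chromStart.size(); ++b) isStart[chromStart[b]] = true;

  IntegerMatrix back(S, N);
  std::vector<double> delta(S), dnew(S);
  IntegerVector path(N);
  int blockStart = 0;
  auto traceback = [&](int last) {
    // argmax at block end, then follow back pointers
    int best = 0;
    for (int s = 1; s < S; ++s) if (delta[s] > delta[best]) best = s;
    for (int i = last; i > blockStart; --i) {
      path[i] = best + 1;
      best = back(best, i);
    }
    path[blockStart] = best + 1;
  };
  for (int i = 0; i < N; ++i) {
    if (isStart[i + 1]) {
      if (i > 0) traceback(i - 1);
      blockStart = i;
      for (int s = 0; s < S; ++s) delta[s] = logPi[s] + logE(s, i);
    } else {
      for (int s = 0; s < S; ++s) {
        double best = -std::numeric_limits<double>::infinity();
        int arg = 0;
        for (int r = 0; r < S; ++r) {
          const double v = delta[r] + logM(r, s);
          if (v > best) { best = v; arg = r; }  // strict > keeps smallest r
        }
        dnew[s] = best + logE(s, i);
        back(s, i) = arg;
      }
      delta = dnew;
    }
  }
  traceback(N - 1);
  return path;
}

// One Baum-Welch E-step (scaled forward-backward) with chromosome resets.
// Returns the log-likelihood, the matrix of expected transition counts,
// and the summed start-of-chromosome posterior (for the initial law).
// [[Rcpp::export]]
List hmm_bw_estep_cpp(const NumericMatrix& logE, const NumericMatrix& M,
                      const NumericVector& pi,
                      const IntegerVector& chromStart) {
  const int S = logE.nrow(), N = logE.ncol();
  std::vector<bool> isStart(N + 1, false);
  for (int b = 0; b < chromStart.size(); ++b) isStart[chromStart[b]] = true;
  NumericMatrix alpha(S, N), beta(S, N), E(S, N);
  std::vector<double> scale(N), emax(N);
  double loglik = 0.0;
  for (int i = 0; i < N; ++i) {
    double m = -std::numeric_limits<double>::infinity();
    for (int s = 0; s < S; ++s) m = std::max(m, logE(s, i));
    emax[i] = m;
    for (int s = 0; s < S; ++s) E(s, i) = std::exp(logE(s, i) - m);
  }
  // forward
  for (int i = 0; i < N; ++i) {
    if (isStart[i + 1]) {
      for (int s = 0; s < S; ++s) alpha(s, i) = pi[s] * E(s, i);
    } else {
      for (int s = 0; s < S; ++s) {
        double acc = 0.0;
        for (int r = 0; r < S; ++r) acc += alpha(r, i - 1) * M(r, s);
        alpha(s, i) = acc * E(s, i);
      }
    }
    double norm = 0.0;
    for (int s = 0; s < S; ++s) norm += alpha(s, i);
    if (norm <= 0.0 || !std::isfinite(norm))
      stop("forward pass underflowed at window %d", i + 1);
    for (int s = 0; s < S; ++s) alpha(s, i) /= norm;
    scale[i] = norm;
    loglik += std::log(norm) + emax[i];
  }
  // backward (scaled by the forward norms)
  for (int i = N - 1; i >= 0; --i) {
    if (i == N - 1 || isStart[i + 2]) {
      for (int s = 0; s < S; ++s) beta(s, i) = 1.0;
    } else {
      for (int r = 0; r < S; ++r) {
        double acc = 0.0;
        for (int s = 0; s < S; ++s)
          acc += M(r, s) * E(s, i + 1) * beta(s, i + 1);
        beta(r, i) = acc / scale[i + 1];
      }
    }
  }
  NumericMatrix xi(S, S);
  NumericVector gammaStart(S);
  for (int i = 0; i < N; ++i) {
    if (isStart[i + 1]) {
      double tot = 0.0;
      for (int s = 0; s < S; ++s) tot += alpha(s, i) * beta(s, i);
      for (int s = 0; s < S; ++s) gammaStart[s] += alpha(s, i) * beta(s, i) / tot;
    }
    if (i + 1 < N && !isStart[i + 2]) {
      for (int r = 0; r < S; ++r) {
        const double a = alpha(r, i);
        if (a == 0.0) continue;
        for (int s = 0; s < S; ++s)
          xi(r, s) += a * M(r, s) * E(s, i + 1) * beta(s, i + 1) / scale[i + 1];
      }
    }
  }
  return List::create(_["loglik"] = loglik, _["xi"] = xi,
                      _["gamma_start"] = gammaStart);
}
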