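#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Penalized optimal partitioning of a series into constant-mean segments.
// Minimizes sum of within-segment SSE + penalty * (number of segments) by
// O(n^2) dynamic programming. Ties are broken toward fewer segments, then
// toward the earliest admissible rightmost breakpoint, applied recursively
// (the candidate change points are scanned in increasing order, so the first
// candidate achieving the optimal (cost, n_segments) is kept).
// Returns 1-based inclusive segment end indices.
// max_lookback > 0 caps segment length (windowed approximation); 0 = exact.
// [[Rcpp::export]]
IntegerVector cpp_dp_segment(NumericVector x, double penalty, int min_seg,
                             int max_lookback) {
  int n = x.size();
  if (n == 0) return IntegerVector(0);
  if (min_seg < 1) min_seg = 1;
  if (n < min_seg) {
    IntegerVector out(1); out[0] = n; return out;
  }
  std::vector<double> S(n + 1, 0.0), S2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    S[i + 1] = S[i] + x[i];
    S2[i + 1] = S2[i] + x[i] * x[i];
  }
  std::vector<double> F(n + 1, R_PosInf);
  std::vector<int> nseg(n + 1, INT_MAX), back(n + 1, -1);
  F[0] = 0.0; nseg[0] = 0;
  // candidate change points, PELT-pruned; pruning only discards candidates
  // that are strictly dominated, so optimum and tie-breaks are unchanged
  std::vector<int> cands; cands.reserve(64); cands.push_back(0);
  std::vector<int> keep; keep.reserve(64);
  for (int t = min_seg; t <= n; ++t) {
    int c_new = t - min_seg;
    if (c_new > 0) cands.push_back(c_new);
    for (size_t ci = 0; ci < cands.size(); ++ci) {
      int s = cands[ci];
      if (s + min_seg > t) continue;
      if (max_lookback > 0 && t - s > max_lookback) continue;
      if (!R_FINITE(F[s])) continue;
      int m = t - s;
      double sum = S[t] - S[s];
      double cost = (S2[t] - S2[s]) - sum * sum / m;
      double c = F[s] + cost + penalty;
      bool take = false;
      if (c < F[t]) take = true;
      else if (c == F[t] && nseg[s] + 1 < nseg[t]) take = true;
      if (take) { F[t] = c; nseg[t] = nseg[s] + 1; back[t] = s; }
    }
    // the dominance argument needs every candidate to be extendable at the
    // next step, which only holds without a minimum-segment constraint
    if (min_seg == 1) {
      keep.clear();
      for (size_t ci = 0; ci < cands.size(); ++ci) {
        int s = cands[ci];
        int m = t - s;
        double sum = S[t] - S[s];
        double cost = (S2[t] - S2[s]) - sum * sum / m;
        if (F[s] + cost <= F[t]) keep.push_back(s);
      }
      cands.swap(keep);
    }
  }
  // fall back for pathological min_seg (no admissible partition): one segment
  if (back[n] < 0) { IntegerVector out(1); out[0] = n; return out; }
  std::vector<int> ends;
  for (int t = n; t > 0; t = back[t]) ends.push_back(t);
  std::reverse(ends.begin(), ends.end());
  return wrap(ends);
}

// Scaled forward-backward for one chromosome chain with transition matrix
// A(d) = (1 - p(d)) I + p(d) 1 pi', where p(d) is the per-step leave
// probability (length n-1). emis: n x K linear emission likelihoods.
// Returns posterior (n x K) and the total log-likelihood.
// [[Rcpp::export]]
List cpp_forward_backward(NumericMatrix emis, NumericVector pleave,
                          NumericVector pi) {
  int n = emis.nrow(), K = emis.ncol();
  NumericMatrix alpha(n, K), beta(n, K), gamma(n, K);
  std::vector<double> cvec(n);
  double ll = 0.0;
  // forward
  double c0 = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * emis(0, k); c0 += alpha(0, k); }
  if (c0 <= 0.0) stop("zero likelihood at locus 1");
  for (int k = 0; k < K; ++k) alpha(0, k) /= c0;
  cvec[0] = c0; ll += std::log(c0);
  for (int t = 1; t < n; ++t) {
    double p = pleave[t - 1], ct = 0.0;
    for (int k = 0; k < K; ++k) {
      double pred = (1.0 - p) * alpha(t - 1, k) + p * pi[k]; // sum(alpha)=1
      alpha(t, k) = pred * emis(t, k);
      ct += alpha(t, k);
    }
    if (ct <= 0.0) stop("zero likelihood at locus %d", t + 1);
    for (int k = 0; k < K; ++k) alpha(t, k) /= ct;
    cvec[t] = ct; ll += std::log(ct);
  }
  // backward (scaled by the forward constants)
  for (int k = 0; k < K; ++k) beta(n - 1, k) = 1.0;
  for (int t = n - 2; t >= 0; --t) {
    double p = pleave[t], mix = 0.0;
    for (int j = 0; j < K; ++j) mix += pi[j] * emis(t + 1, j) * beta(t + 1, j);
    for (int k = 0; k < K; ++k) {
      double v = (1.0 - p) * emis(t + 1, k) * beta(t + 1, k) + p * mix;
      beta(t, k) = v / cvec[t + 1];
    }
  }
  for (int t = 0; t < n; ++t) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); s += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= s;
  }
  return List::create(_["posterior"] = gamma, _["loglik"] = ll);
}

// Viterbi decoding under the same transition model, in log space.
// Ties are broken toward `normal` (1-based state index), both in the
// per-step argmax and at the final state. Returns 1-based state indices.
// [[Rcpp::export]]
IntegerVector cpp_viterbi(NumericMatrix emis, NumericVector pleave,
                          NumericVector pi, int normal) {
  int n = emis.nrow(), K = emis.ncol();
  int nrm = normal - 1;
  NumericMatrix delta(n, K);
  IntegerMatrix psi(n, K);
  for (int k = 0; k < K; ++k)
    delta(0, k) = std::log(pi[k]) + std::log(emis(0, k));
  for (int t = 1; t < n; ++t) {
    double p = pleave[t - 1];
    for (int j = 0; j < K; ++j) {
      // order: try the normal state first so exact ties keep it
      double best = R_NegInf; int arg = nrm;
      for (int q = 0; q < K; ++q) {
        int k = (q == 0) ? nrm : (q <= nrm ? q - 1 : q);
        double a = (k == j) ? (1.0 - p) + p * pi[j] : p * pi[j];
        double v = delta(t - 1, k) + std::log(a);
        if (v > best) { best = v; arg = k; }
      }
      delta(t, j) = best + std::log(emis(t, j));
      psi(t, j) = arg;
    }
  }
  double best = R_NegInf; int arg = nrm;
  for (int q = 0; q < K; ++q) {
    int k = (q == 0) ? nrm : (q <= nrm ? q - 1 : q);
    if (delta(n - 1, k) > best) { best = delta(n - 1, k); arg = k; }
  }
  IntegerVector path(n);
  path[n - 1] = arg + 1;
  for (int t = n - 1; t > 0; --t) {
    arg = psi(t, arg);
    path[t - 1] = arg + 1;
  }
  return path;
}
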