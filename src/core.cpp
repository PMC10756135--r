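#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Causal FIR convolution y[n] = sum_k b[k] x[n-k] with zero-padded history.
// [[Rcpp::export]]
NumericVector fir_core(NumericVector x, NumericVector b) {
  const int n = x.size(), nb = b.size();
  if (nb < 1) stop("empty coefficient vector");
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    const int kmax = std::min(i, nb - 1);
    for (int k = 0; k <= kmax; ++k) acc += b[k] * x[i - k];
    y[i] = acc;
  }
  return y;
}

// Streaming dynamic-gradient peak/trough detector.
//
// Per sample: maintain window sum / sum-of-squares over the trailing M
// samples (two accumulators plus the eviction value read back from the
// input), derive gradient = RMS * (CV/100) * gain with CV = 100*sd/|mean|
// (0 for zero mean magnitude), then advance the local-max/min state
// machine.  Retained state is O(1) in the trace length.
// [[Rcpp::export]]
List detect_core(NumericVector x, int M, double gain, double warmup_frac) {
  const int n = x.size();
  if (n < 1) stop("empty trace");
  if (M < 1) stop("window must be >= 1");
  const int warm = (int)std::ceil(warmup_frac * M);

  double s = 0.0, s2 = 0.0;
  double lmax_v = R_NegInf, lmin_v = R_PosInf;
  int lmax_i = -1, lmin_i = -1;
  bool emission = true;

  std::vector<int> kind, idx;
  std::vector<double> val;

  for (int i = 0; i < n; ++i) {
    const double v = x[i];
    s += v;
    s2 += v * v;
    if (i >= M) {
      const double e = x[i - M];
      s -= e;
      s2 -= e * e;
    }
    const int m = (i + 1 < M) ? (i + 1) : M;
    const double mu = s / m;
    const double ms = s2 / m;
    double var = ms - mu * mu;
    if (var < 0.0) var = 0.0;
    const double sd = std::sqrt(var);
    const double rms = std::sqrt(ms > 0.0 ? ms : 0.0);
    const double am = std::fabs(mu);
    const double cv = (am > 0.0) ? (100.0 * sd / am) : 0.0;
    const double grad = rms * (cv / 100.0) * gain;

    if (v > lmax_v) { lmax_v = v; lmax_i = i; }
    if (v < lmin_v) { lmin_v = v; lmin_i = i; }

    if (i + 1 >= warm) {
      if (emission && v < lmax_v - grad) {
        emission = false;
        kind.push_back(1); idx.push_back(lmax_i); val.push_back(lmax_v);
        lmin_v = lmax_v; lmin_i = lmax_i;
      } else if (!emission && v > lmin_v + grad) {
        emission = true;
        kind.push_back(-1); idx.push_back(lmin_i); val.push_back(lmin_v);
        lmax_v = lmin_v; lmax_i = lmin_i;
      }
    }
  }

  // Fixed-length accumulator snapshot: the detector's entire retained state.
  NumericVector state = NumericVector::create(
    _["sum"] = s, _["sumsq"] = s2,
    _["local_max_value"] = lmax_v, _["local_max_index"] = (double)lmax_i,
    _["local_min_value"] = lmin_v, _["local_min_index"] = (double)lmin_i,
    _["is_emission"] = emission ? 1.0 : 0.0,
    _["samples_seen"] = (double)n);

  return List::create(
    _["kind"] = wrap(kind),
    _["index"] = wrap(idx),
    _["value"] = wrap(val),
    _["state"] = state);
}
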