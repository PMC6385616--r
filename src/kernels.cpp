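#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Fast Gaussian white-noise matrix (xoshiro256+ with polar Box-Muller),
// deterministically seeded from the R RNG stream by the caller. Used for
// the bulk sensor-noise innovations where R's rnorm dominates runtime.
static inline uint64_t rotl(const uint64_t x, int k) {
  return (x << k) | (x >> (64 - k));
}

// [[Rcpp::export]]
NumericMatrix cpp_white_noise(int n, int m, double seed) {
  NumericMatrix out(n, m);
  uint64_t s[4];
  // splitmix64 expansion of the seed
  uint64_t z = (uint64_t)seed;
  for (int i = 0; i < 4; ++i) {
    z += 0x9e3779b97f4a7c15ULL;
    uint64_t t = z;
    t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
    t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
    s[i] = t ^ (t >> 31);
  }
  auto next = [&]() -> uint64_t {
    const uint64_t result = s[0] + s[3];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  };
  auto unif = [&]() -> double {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  };
  double* p = out.begin();
  const R_xlen_t total = (R_xlen_t)n * m;
  R_xlen_t i = 0;
  while (i < total) {
    double u = 2.0 * unif() - 1.0, v = 2.0 * unif() - 1.0;
    double r2 = u * u + v * v;
    if (r2 >= 1.0 || r2 == 0.0) continue;
    double f = std::sqrt(-2.0 * std::log(r2) / r2);
    p[i++] = u * f;
    if (i < total) p[i++] = v * f;
  }
  return out;
}

// Per-trial, per-channel peak-to-peak range of an epochs array laid out as
// (trial, channel, sample).
// [[Rcpp::export]]
NumericMatrix cpp_ptp(NumericVector data, int n_trials, int n_channels,
                      int n_samples) {
  NumericMatrix out(n_trials, n_channels);
  const double* p = data.begin();
  std::vector<double> mn((size_t)n_trials * n_channels, R_PosInf);
  std::vector<double> mx((size_t)n_trials * n_channels, R_NegInf);
  const size_t tc = (size_t)n_trials * n_channels;
  for (int s = 0; s < n_samples; ++s) {
    const double* slice = p + (size_t)s * tc;
    for (size_t j = 0; j < tc; ++j) {
      const double v = slice[j];
      if (v < mn[j]) mn[j] = v;
      if (v > mx[j]) mx[j] = v;
    }
  }
  for (size_t j = 0; j < tc; ++j) out[j] = mx[j] - mn[j];
  return out;
}

// Gather epochs from a continuous recording (samples x channels) directly
// into the (trial, channel, sample) layout. events/channels are 1-based.
// [[Rcpp::export]]
NumericVector cpp_epoch_grab(NumericMatrix data, IntegerVector events,
                             int i0, int n_samples, IntegerVector channels) {
  const int nt = events.size(), nc = channels.size();
  NumericVector out((R_xlen_t)nt * nc * n_samples);
  double* o = out.begin();
  const double* d = data.begin();
  const int nrow = data.nrow();
  for (int s = 0; s < n_samples; ++s)
    for (int c = 0; c < nc; ++c) {
      const double* col = d + (size_t)(channels[c] - 1) * nrow;
      const size_t base = (size_t)s * nt * nc + (size_t)c * nt;
      for (int t = 0; t < nt; ++t)
        o[base + t] = col[events[t] - 1 + i0 + s];
    }
  out.attr("dim") = IntegerVector::create(nt, nc, n_samples);
  return out;
}

// Direct-form-II-transposed IIR filter, a[0] assumed 1.
// [[Rcpp::export]]
NumericVector cpp_ba_filter(NumericVector b, NumericVector a,
                            NumericVector x) {
  const int nb = b.size(), na = a.size(), n = x.size();
  const int nw = std::max(nb, na);
  std::vector<double> w(nw, 0.0);
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + w[0];
    for (int k = 1; k < nw; ++k)
      w[k - 1] = (k < nb ? b[k] * xi : 0.0) - (k < na ? a[k] * yi : 0.0) +
        (k < nw - 1 ? w[k] : 0.0);
    y[i] = yi;
  }
  return y;
}
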