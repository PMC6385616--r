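#include <Rcpp.h>
using namespace Rcpp;

// Cascade of first-order pole/zero sections applied column-wise.
// Each section is H(q) = (1 - z_k q^-1) / (1 - p_k q^-1); the caller chooses
// log-spaced corner frequencies so the cascade's magnitude response follows
// f^(-alpha/2) over the band of interest (staircase approximation).
// [[Rcpp::export]]
NumericMatrix cpp_iir_cascade(NumericMatrix x, NumericVector poles,
                              NumericVector zeros) {
  const int n = x.nrow(), m = x.ncol(), k = poles.size();
  if (zeros.size() != k) stop("poles and zeros must have equal length");
  NumericMatrix y(n, m);
  for (int j = 0; j < m; ++j) {
    // work buffer for this column
    std::vector<double> buf(n);
    for (int i = 0; i < n; ++i) buf[i] = x(i, j);
    for (int s = 0; s < k; ++s) {
      const double p = poles[s], z = zeros[s];
      double x1 = 0.0, y1 = 0.0;
      for (int i = 0; i < n; ++i) {
        const double xi = buf[i];
        const double yi = xi - z * x1 + p * y1;
        buf[i] = yi;
        x1 = xi;
        y1 = yi;
      }
    }
    for (int i = 0; i < n; ++i) y(i, j) = buf[i];
  }
  return y;
}

// Build the sensor-channel matrix in one pass: channel j receives
// weights[j] * osc plus 1/f-shaped, unit-variance-normalized noise scaled by
// noise_amp. `white` supplies the white-noise innovations (n x n_channels).
// [[Rcpp::export]]
NumericMatrix cpp_mix_channels(NumericVector osc, NumericVector weights,
                               NumericMatrix white, NumericVector poles,
                               NumericVector zeros, double noise_amp) {
  const int n = osc.size(), m = weights.size(), k = poles.size();
  if (white.nrow() != n || white.ncol() != m)
    stop("white noise matrix must be n_samples x n_channels");
  NumericMatrix y(n, m);
  std::vector<double> buf(n);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) buf[i] = white(i, j);
    for (int s = 0; s < k; ++s) {
      const double p = poles[s], z = zeros[s];
      double x1 = 0.0, y1 = 0.0;
      for (int i = 0; i < n; ++i) {
        const double xi = buf[i];
        const double yi = xi - z * x1 + p * y1;
        buf[i] = yi;
        x1 = xi;
        y1 = yi;
      }
    }
    double s1 = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) { s1 += buf[i]; s2 += buf[i] * buf[i]; }
    const double mu = s1 / n;
    const double sd = std::sqrt(s2 / n - mu * mu);
    const double scale = sd > 0 ? noise_amp / sd : 0.0;
    const double w = weights[j];
    for (int i = 0; i < n; ++i) y(i, j) = w * osc[i] + scale * buf[i];
  }
  return y;
}
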