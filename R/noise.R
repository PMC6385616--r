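#' Generate 1/f^alpha ("pink") noise channels
#'
#' Spectrally shapes white Gaussian noise into power-law noise with target
#' power spectral density proportional to `f^-alpha` between `f_lo` and
#' `f_hi`. Shaping uses a cascade of first-order pole/zero sections with
#' log-spaced corner frequencies (a staircase approximation of the power-law
#' magnitude response); each output channel is rescaled to unit standard
#' deviation.
#'
#' @param n Number of samples per channel.
#' @param n_channels Number of independent channels.
#' @param sfreq Sampling frequency in Hz.
#' @param exponent Spectral exponent alpha (default 1).
#' @param f_lo,f_hi Band over which the power law is enforced; defaults span
#'   0.5 Hz to 40% of the Nyquist frequency.
#' @param sections_per_decade Pole/zero pairs per frequency decade
#'   (default 3; more sections give smaller staircase ripple).
#'
#' @return An `n x n_channels` matrix of unit-variance noise.
#' @export
pink_noise <- function(n, n_channels = 1, sfreq = 1000, exponent = 1,
                       f_lo = 0.5, f_hi = 0.4 * sfreq / 2,
                       sections_per_decade = 3) {
  white <- matrix(stats::rnorm(n * n_channels), n, n_channels)
  if (exponent == 0) return(white)
  co <- pink_cascade_coefs(sfreq, exponent, f_lo, f_hi, sections_per_decade)
  out <- cpp_iir_cascade(white, co$poles, co$zeros)
  sds <- sqrt(colMeans(out ^ 2) - colMeans(out) ^ 2)
  sweep(out, 2, sds, "/")
}

# log-spaced pole/zero corner frequencies mapped to the unit circle
pink_cascade_coefs <- function(sfreq, exponent, f_lo = 0.5,
                               f_hi = 0.4 * sfreq / 2,
                               sections_per_decade = 3) {
  decades <- log10(f_hi / f_lo)
  k <- max(1L, ceiling(sections_per_decade * decades))
  fp <- f_lo * 10 ^ ((seq_len(k) - 1) / sections_per_decade)
  fz <- fp * 10 ^ (exponent / (2 * sections_per_decade))
  list(poles = exp(-2 * pi * fp / sfreq), zeros = exp(-2 * pi * fz / sfreq))
}
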