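# Shared fixtures: epoch containers built in code and small configurations.

mk_epochs <- function(data, sfreq = 1000, tmin = -1.5, types = NULL,
                      pairs = NULL) {
  if (is.matrix(data)) data <- array(data, dim = c(nrow(data), 1, ncol(data)))
  nc <- dim(data)[2]; ns <- dim(data)[3]
  if (is.null(types)) types <- rep("grad", nc)
  if (is.null(pairs)) pairs <- rep(seq_len(ceiling(nc / 2)), each = 2)[seq_len(nc)]
  structure(list(
    data = data,
    times = seq(tmin, by = 1 / sfreq, length.out = ns),
    tmin = tmin, sfreq = sfreq,
    info = data.frame(name = paste0("ch", seq_len(nc)), type = types,
                      pair = pairs, unit = "au", stringsAsFactors = FALSE),
    trial_ids = seq_len(dim(data)[1]),
    rejection_log = data.frame(trial = seq_len(dim(data)[1]), kept = TRUE,
                               reason = "", stringsAsFactors = FALSE)),
    class = "epochs_set")
}

# a small, fast study configuration (short ITI and rebound window)
tiny_config <- function(...) {
  args <- list(n_pd = 2, n_hc = 2, n_sessions = 1, n_trials = 8, n_pairs = 2,
               iti_range = c(2.0, 2.3), rebound_window = c(0.5, 1.2),
               seed = 7)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

# single-trial band power (mean squared FFT magnitude over band), an
# independent frequency-domain oracle used by the induced-response tests
band_power <- function(x, sfreq, band) {
  n <- length(x)
  f <- (seq_len(n) - 1) * sfreq / n
  p <- Mod(stats::fft(x)) ^ 2
  sum(p[f >= band[1] & f <= band[2]])
}

# analytic-signal band amplitude (FFT brickwall + Hilbert magnitude)
band_amplitude <- function(x, sfreq, band) {
  n <- length(x)
  f <- (seq_len(n) - 1) * sfreq / n
  X <- stats::fft(x)
  X[!(f >= band[1] & f <= band[2])] <- 0
  2 * Mod(stats::fft(X, inverse = TRUE)) / n
}
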