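# Accelerometer and EMG conditioning.

# direct-form IIR filter (a[1] assumed 1)
ba_filter <- function(b, a, x) cpp_ba_filter(b, a, x)

# zero-phase (forward-backward) filtering with odd-reflection edge padding
zp_filter <- function(x, flt) {
  b <- flt$b
  a <- flt$a
  n <- length(x)
  p <- min(n - 1, 1000L)
  xx <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- ba_filter(b, a, xx)
  y <- rev(ba_filter(b, a, rev(y)))
  y[(p + 1):(p + n)]
}

#' Band-passed, z-scored accelerometer norm
#'
#' Band-pass filters the three orthogonal accelerometer axes (zero-phase
#' Butterworth), collapses them to the per-sample Euclidean norm, and
#' z-scores the norm over the whole session, giving an orientation-invariant
#' movement trace with mean 0 and SD 1.
#'
#' @param acc A `3 x samples` or `samples x 3` numeric matrix.
#' @param sfreq Sampling frequency in Hz; must exceed twice the upper band
#'   edge.
#' @param band Pass band in Hz (default `c(1, 195)`).
#' @param order Butterworth order (default 3).
#' @return Numeric vector: the z-scored movement norm.
#' @export
accelerometer_norm <- function(acc, sfreq, band = c(1, 195), order = 3) {
  if (is.vector(acc)) stop("accelerometer input needs 3 axes")
  if (nrow(acc) == 3 && ncol(acc) != 3) acc <- t(acc)
  if (ncol(acc) != 3) stop("accelerometer input needs 3 axes")
  if (sfreq <= 2 * band[2])
    stop("sfreq must exceed twice the upper band edge")
  flt <- signal::butter(order, band / (sfreq / 2), type = "pass")
  filt <- apply(acc, 2, zp_filter, flt = flt)
  nrm <- sqrt(rowSums(filt ^ 2))
  as.numeric(scale(nrm))
}

#' Flag trials with accidental movements outside the stimulus window
#'
#' A trial is flagged iff the z-scored accelerometer norm exceeds `z_thr`
#' in magnitude for at least `min_dur` contiguous seconds at any time
#' outside the stimulus window. Flagged trials are rejected from the epochs
#' with reason `"movement"`.
#'
#' @param acc_epochs Matrix `trials x samples` of the z-scored accelerometer
#'   norm, aligned to events.
#' @param times Time axis of the epochs in seconds.
#' @param window Stimulus window in seconds that movement is allowed to
#'   occupy (default `c(0, 0.5)`).
#' @param z_thr Threshold on `|z|` (default 3).
#' @param min_dur Minimum contiguous supra-threshold duration in seconds
#'   (default 0.02).
#' @param epochs Optional `epochs_set` (with matching trials) from which
#'   flagged trials are dropped.
#' @return If `epochs` is `NULL`, a logical vector of per-trial flags;
#'   otherwise a list with `flags` and the filtered `epochs`.
#' @export
flag_accidental_movements <- function(acc_epochs, times, window = c(0, 0.5),
                                      z_thr = 3, min_dur = 0.02,
                                      epochs = NULL) {
  if (window[1] < min(times) || window[2] > max(times) + 1e-9)
    stop("stimulus window must lie within the epoch span")
  dt <- times[2] - times[1]
  min_n <- max(1L, as.integer(round(min_dur / dt)))
  outside <- times < window[1] | times > window[2]
  flags <- apply(acc_epochs, 1, function(tr) {
    above <- abs(tr) > z_thr & outside
    r <- rle(above)
    any(r$values & r$lengths >= min_n)
  })
  if (is.null(epochs)) return(flags)
  list(flags = flags,
       epochs = drop_trials(epochs, which(flags), "movement"))
}

#' Condition EMG epochs: line-noise suppression, rectification, PSD
#'
#' Suppresses the 50 Hz line component with a zero-phase notch filter,
#' rectifies (absolute value), averages the rectified trials for the
#' session, and computes the Hann-windowed power spectral density of the
#' non-rectified signals (average periodogram across trials).
#'
#' @param emg_epochs Matrix `trials x samples` of the EMG channel.
#' @param sfreq Sampling frequency in Hz.
#' @param line_freq Line frequency to suppress (default 50 Hz).
#' @return List with `rectified` (trials x samples), `average` (per-sample
#'   across-trial mean of the rectified epochs), and `psd` (data frame
#'   `freq`, `power`).
#' @export
preprocess_emg <- function(emg_epochs, sfreq, line_freq = 50) {
  if (is.null(dim(emg_epochs))) emg_epochs <- matrix(emg_epochs, nrow = 1)
  notch <- signal::butter(2, c(line_freq - 2, line_freq + 2) / (sfreq / 2),
                          type = "stop")
  filtered <- t(apply(emg_epochs, 1, zp_filter, flt = notch))
  rectified <- abs(filtered)
  ns <- ncol(emg_epochs)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(ns) / (ns + 1)))
  spec <- Mod(stats::mvfft(t(emg_epochs * rep(win, each = nrow(emg_epochs))))) ^ 2
  nf <- floor(ns / 2)
  psd <- data.frame(freq = (seq_len(nf) - 1) * sfreq / ns,
                    power = rowMeans(spec[seq_len(nf), , drop = FALSE]))
  list(rectified = rectified, average = colMeans(rectified), psd = psd)
}
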