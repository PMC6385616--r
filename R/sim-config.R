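#' Simulation configuration for a synthetic passive-movement study
#'
#' Defines the generative parameters of a synthetic event-locked oscillatory
#' study: two subject groups (patients, `pd`, and healthy controls, `hc`)
#' recorded in one or more sessions, each session containing a fixed number of
#' passive-movement events separated by a jittered silent period. Each event
#' modulates ongoing mu/beta carrier oscillations with an event-related
#' desynchronization (ERD) during the movement window followed by a rebound
#' (ERS) whose amplitude gain carries the group-by-session effect under study.
#'
#' Channels are abstract planar-gradiometer-like pair members (no forward
#' model): each of the `2 * n_pairs` sensor channels receives the common
#' oscillatory signal with its own random mixing weight plus independent
#' 1/f^alpha noise. An EMG channel (broadband noise, 50 Hz line component,
#' optional spurious bursts) and three accelerometer channels (the stimulus
#' movement profile plus optional accidental movements) are appended.
#'
#' @param n_pd,n_hc Number of subjects per group.
#' @param n_sessions Sessions per subject (default 2).
#' @param n_trials Passive-movement events per session (default 90).
#' @param sfreq Sampling frequency in Hz (default 1000).
#' @param n_pairs Number of orthogonal channel pairs (default 10).
#' @param iti_range Inter-trial silent period in seconds, drawn uniformly
#'   (default `c(3.5, 4)`).
#' @param carrier_freqs Carrier frequencies in Hz of the modulated rhythms
#'   (default mu 10 Hz, beta 20 Hz).
#' @param baseline_amp Baseline amplitude of each carrier, in the recording's
#'   (arbitrary, gradiometer-like) units.
#' @param erd_depth Fractional amplitude suppression during the ERD window,
#'   in `[0, 1]`. Scalar (all cells) or a `2 x n_sessions` matrix with rows
#'   `pd`, `hc`.
#' @param rebound_gain Fractional amplitude increase during the rebound
#'   window, `>= 0`. Scalar or a `2 x n_sessions` matrix with rows `pd`, `hc`.
#'   The default encodes an attenuated patient rebound (`pd` 0.15, `hc` 0.8,
#'   both sessions).
#' @param erd_window,rebound_window Seconds relative to the event at which
#'   the ERD and rebound plateaus sit (defaults `[0, 0.5]` and `[0.5, 1.5]`).
#' @param ramp Raised-cosine transition duration between envelope plateaus,
#'   in seconds (default 0.1).
#' @param evoked_amp Amplitude of the phase-locked evoked transient peaking
#'   at `evoked_peak` seconds after the event.
#' @param evoked_peak Latency of the evoked transient peak in seconds; must
#'   lie in the 50--110 ms post-stimulus interval (default 0.08).
#' @param noise_amp Standard deviation of the additive per-channel
#'   1/f^alpha noise.
#' @param noise_exponent Spectral exponent alpha of the noise (default 1).
#' @param emg_burst_prob Per-trial probability of a spurious EMG burst
#'   (default 0).
#' @param acc_movement_prob Per-trial probability of an accidental finger
#'   movement outside the stimulus window (default 0).
#' @param seed Integer RNG seed. Identical configurations and seeds yield
#'   bit-identical synthetic data.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_study()], [simulate_trial_signal()], [make_envelope()]
#' @export
sim_config <- function(n_pd = 12, n_hc = 16, n_sessions = 2, n_trials = 90,
                       sfreq = 1000, n_pairs = 10, iti_range = c(3.5, 4),
                       carrier_freqs = c(mu = 10, beta = 20),
                       baseline_amp = c(20, 20),
                       erd_depth = 0.5,
                       rebound_gain = matrix(c(0.15, 0.8), nrow = 2, ncol = n_sessions,
                                             dimnames = list(c("pd", "hc"), NULL)),
                       erd_window = c(0, 0.5), rebound_window = c(0.5, 1.5),
                       ramp = 0.1, evoked_amp = 60, evoked_peak = 0.08,
                       noise_amp = 15, noise_exponent = 1,
                       emg_burst_prob = 0, acc_movement_prob = 0,
                       seed = 1L) {
  counts <- c(n_pd = n_pd, n_hc = n_hc, n_sessions = n_sessions,
              n_trials = n_trials, n_pairs = n_pairs)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all counts (n_pd, n_hc, n_sessions, n_trials, n_pairs) must be integers >= 1")
  if (length(iti_range) != 2 || iti_range[1] > iti_range[2] || iti_range[1] <= 0)
    stop("iti_range must be an increasing positive interval")
  if (length(baseline_amp) != length(carrier_freqs))
    stop("baseline_amp must have one entry per carrier frequency")
  expand_cell <- function(x, what) {
    if (length(x) == 1) x <- matrix(x, 2, n_sessions)
    x <- as.matrix(x)
    if (!all(dim(x) == c(2, n_sessions)))
      stop(sprintf("%s must be a scalar or a 2 x n_sessions matrix (rows pd, hc)", what))
    rownames(x) <- c("pd", "hc")
    x
  }
  erd_depth <- expand_cell(erd_depth, "erd_depth")
  rebound_gain <- expand_cell(rebound_gain, "rebound_gain")
  if (any(erd_depth < 0 | erd_depth > 1)) stop("erd_depth must lie in [0, 1]")
  if (any(rebound_gain < 0)) stop("rebound_gain must be >= 0")
  if (erd_window[2] > rebound_window[1])
    stop("erd_window and rebound_window must not overlap")
  if (ramp <= 0) stop("ramp must be > 0")
  if (evoked_peak < 0.05 || evoked_peak > 0.11)
    stop("evoked_peak must lie within [0.05, 0.11] s")
  if (rebound_window[2] + ramp > iti_range[1])
    stop("invalid timing: the envelope (rebound_window end + ramp) must fit inside the minimum inter-trial interval")
  cfg <- list(n_pd = as.integer(n_pd), n_hc = as.integer(n_hc),
              n_sessions = as.integer(n_sessions), n_trials = as.integer(n_trials),
              sfreq = sfreq, n_pairs = as.integer(n_pairs), iti_range = iti_range,
              carrier_freqs = carrier_freqs, baseline_amp = baseline_amp,
              erd_depth = erd_depth, rebound_gain = rebound_gain,
              erd_window = erd_window, rebound_window = rebound_window,
              ramp = ramp, evoked_amp = evoked_amp, evoked_peak = evoked_peak,
              noise_amp = noise_amp, noise_exponent = noise_exponent,
              emg_burst_prob = emg_burst_prob, acc_movement_prob = acc_movement_prob,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  subjects: %d pd + %d hc, %d session(s), %d trials/session\n",
              x$n_pd, x$n_hc, x$n_sessions, x$n_trials))
  cat(sprintf("  sfreq %g Hz, %d channel pairs, ITI %.2f-%.2f s\n",
              x$sfreq, x$n_pairs, x$iti_range[1], x$iti_range[2]))
  cat(sprintf("  carriers %s Hz; ERD depth (s1) pd %.2f / hc %.2f; rebound gain (s1) pd %.2f / hc %.2f\n",
              paste(x$carrier_freqs, collapse = ", "),
              x$erd_depth["pd", 1], x$erd_depth["hc", 1],
              x$rebound_gain["pd", 1], x$rebound_gain["hc", 1]))
  invisible(x)
}

# Deterministic per-subject-per-session seed stream derived from the master
# seed; kept below 2^31 - 1.
session_seed <- function(seed, subject_idx, session_idx) {
  as.integer((as.numeric(seed) * 48271 + subject_idx * 1009 + session_idx * 31) %%
               2147483647)
}
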