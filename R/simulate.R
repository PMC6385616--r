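# Synthetic study generator: event-locked oscillatory recordings with
# gradiometer-like channel pairs plus EMG and accelerometer side channels.

# phase-locked evoked transient: Gaussian bump peaking `peak` s after the event
evoked_template <- function(sfreq, amp, peak, sigma = 0.02) {
  tt <- seq(0, peak + 4 * sigma, by = 1 / sfreq)
  amp * exp(-(tt - peak) ^ 2 / (2 * sigma ^ 2))
}

# stimulus movement profile: one contraction-extension of the actuator within
# 200 ms of the event; biphasic acceleration pulses (derivative-of-Gaussian)
# at the contraction (~25 ms) and extension (~225 ms) onsets, peak magnitude 1
acc_stim_template <- function(sfreq) {
  tt <- seq(0, 0.3, by = 1 / sfreq)
  dgauss <- function(t0, sigma) -(tt - t0) / sigma ^ 2 * exp(-(tt - t0) ^ 2 / (2 * sigma ^ 2))
  prof <- dgauss(0.025, 0.008) - dgauss(0.225, 0.008)
  prof / max(abs(prof))
}

# accidental finger movement: 0.3 s enveloped wiggle, peak magnitude `mag`
acc_accident_template <- function(sfreq, mag) {
  tt <- seq(0, 0.3, by = 1 / sfreq)
  win <- sin(pi * tt / 0.3) ^ 2
  mag * win * sin(2 * pi * 8 * tt)
}

add_at <- function(x, template, starts) {
  nt <- length(template)
  n <- length(x)
  for (s in starts) {
    idx <- s:min(n, s + nt - 1)
    x[idx] <- x[idx] + template[seq_along(idx)]
  }
  x
}

channel_info_for <- function(n_pairs) {
  grad <- data.frame(
    name = paste0("MEG", rep(seq_len(n_pairs), each = 2), c("A", "B")),
    type = "grad",
    pair = rep(seq_len(n_pairs), each = 2),
    unit = "fT/cm", stringsAsFactors = FALSE)
  other <- data.frame(
    name = c("EMG", "ACC_X", "ACC_Y", "ACC_Z"),
    type = c("emg", "acc", "acc", "acc"),
    pair = NA_integer_,
    unit = c("uV", "au", "au", "au"), stringsAsFactors = FALSE)
  rbind(grad, other)
}

#' Simulate the sensor signal of a single epoch
#'
#' Generates one epoch of gradiometer-pair channels for a given group and
#' session cell: envelope-modulated carrier sinusoids with a per-trial
#' uniform random phase, a phase-locked evoked transient, and independent
#' 1/f noise per channel. The two members of each channel pair receive the
#' common signal with independent mixing weights.
#'
#' @param config A [sim_config()].
#' @param group `"pd"` or `"hc"`.
#' @param session Session index.
#' @param window Epoch window in seconds relative to the event.
#' @param weights Optional vector of `2 * n_pairs` mixing weights; drawn
#'   uniformly from `[0.3, 1]` when `NULL`.
#' @return A `channels x samples` matrix of the gradiometer channels, with
#'   attributes `times` and `weights`.
#' @export
simulate_trial_signal <- function(config, group = "pd", session = 1,
                                  window = c(-1.5, 3.5), weights = NULL) {
  stopifnot(inherits(config, "sim_config"))
  group <- match.arg(group, c("pd", "hc"))
  sf <- config$sfreq
  times <- seq(window[1], window[2], by = 1 / sf)
  env <- make_envelope(times, config$erd_window, config$rebound_window,
                       config$erd_depth[group, session],
                       config$rebound_gain[group, session], config$ramp)
  osc <- numeric(length(times))
  for (j in seq_along(config$carrier_freqs)) {
    phi <- stats::runif(1, 0, 2 * pi)
    osc <- osc + config$baseline_amp[j] *
      sin(2 * pi * config$carrier_freqs[j] * times + phi)
  }
  osc <- osc * env
  if (config$evoked_amp != 0) {
    sel <- times >= 0
    tmpl <- evoked_template(sf, config$evoked_amp, config$evoked_peak)
    k <- min(sum(sel), length(tmpl))
    osc[which(sel)[seq_len(k)]] <- osc[which(sel)[seq_len(k)]] + tmpl[seq_len(k)]
  }
  nch <- 2L * config$n_pairs
  if (is.null(weights)) weights <- stats::runif(nch, 0.3, 1)
  sig <- outer(weights, osc)
  if (config$noise_amp > 0)
    sig <- sig + config$noise_amp *
      t(pink_noise(length(times), nch, sf, config$noise_exponent))
  attr(sig, "times") <- times
  attr(sig, "weights") <- weights
  sig
}

#' Simulate one subject-session continuous recording
#'
#' Internal workhorse behind [simulate_study()], exposed so large studies can
#' be processed one subject-session at a time without materializing the whole
#' study. Events are separated by uniform draws from the configured
#' inter-trial interval; the recording carries gradiometer-pair channels, an
#' EMG channel, and three accelerometer channels.
#'
#' @param config A [sim_config()].
#' @param group `"pd"` or `"hc"`.
#' @param session Session index.
#' @param seed Integer seed for this subject-session.
#' @return A `continuous_recording`: list with `data` (samples x channels
#'   matrix), `info` (channel table), `sfreq`, `events` (1-based sample
#'   indices), and a `trials` data frame of ground-truth per-trial flags.
#' @export
simulate_session <- function(config, group = "pd", session = 1, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  group <- match.arg(group, c("pd", "hc"))
  set.seed(seed)
  sf <- config$sfreq
  nt <- config$n_trials
  itis <- stats::runif(nt, config$iti_range[1], config$iti_range[2])
  event_t <- cumsum(itis)
  total <- event_t[nt] + config$iti_range[2]
  n <- ceiling(total * sf) + 1L
  events <- as.integer(round(event_t * sf)) + 1L
  t <- (seq_len(n) - 1) / sf

  # continuous amplitude envelope: each event stamps the same local envelope
  tloc <- seq(config$erd_window[1], config$rebound_window[2] + config$ramp,
              by = 1 / sf)
  env_tmpl <- make_envelope(tloc, config$erd_window, config$rebound_window,
                            config$erd_depth[group, session],
                            config$rebound_gain[group, session], config$ramp)
  offs <- as.integer(round(tloc * sf))
  env <- rep(1, n)
  for (ev in events) env[ev + offs] <- env_tmpl

  osc <- numeric(n)
  for (j in seq_along(config$carrier_freqs)) {
    phi <- stats::runif(1, 0, 2 * pi)
    osc <- osc + config$baseline_amp[j] *
      sin(2 * pi * config$carrier_freqs[j] * t + phi)
  }
  osc <- osc * env
  if (config$evoked_amp != 0)
    osc <- add_at(osc, evoked_template(sf, config$evoked_amp, config$evoked_peak),
                  events)

  nch <- 2L * config$n_pairs
  weights <- stats::runif(nch, 0.3, 1)
  if (config$noise_amp > 0) {
    co <- pink_cascade_coefs(sf, config$noise_exponent)
    # bulk innovations from a fast generator seeded off the R RNG stream
    wseed <- floor(stats::runif(1) * 2 ^ 31)
    meg <- cpp_mix_channels(osc, weights, cpp_white_noise(n, nch, wseed),
                            co$poles, co$zeros, config$noise_amp)
  } else {
    meg <- tcrossprod(osc, weights)
  }

  # EMG: broadband noise + 50 Hz line + optional spurious bursts
  emg <- stats::rnorm(n, sd = 10) + 3 * sin(2 * pi * 50 * t)
  emg_burst <- stats::runif(nt) < config$emg_burst_prob
  if (any(emg_burst)) {
    for (ev in events[emg_burst]) {
      lat <- stats::runif(1, 0.1, 0.3)
      bt <- seq(0, 0.2, by = 1 / sf)
      burst <- 50 * sin(pi * bt / 0.2) ^ 2 * stats::rnorm(length(bt))
      emg <- add_at(emg, burst, ev + as.integer(round(lat * sf)))
    }
  }

  # accelerometer: stimulus profile on a random fixed orientation + noise,
  # optional accidental movements outside the stimulus window
  u <- stats::rnorm(3)
  u <- u / sqrt(sum(u ^ 2))
  prof <- numeric(n)
  prof <- add_at(prof, acc_stim_template(sf), events)
  acc_accident <- stats::runif(nt) < config$acc_movement_prob
  if (any(acc_accident)) {
    lat_lo <- 0.7
    lat_hi <- max(lat_lo + 0.01, min(1.7, config$iti_range[1] - 0.4))
    tmpl <- acc_accident_template(sf, 5)
    for (ev in events[acc_accident]) {
      lat <- stats::runif(1, lat_lo, lat_hi)
      prof <- add_at(prof, tmpl, ev + as.integer(round(lat * sf)))
    }
  }
  acc <- tcrossprod(prof, u) + matrix(stats::rnorm(3 * n, sd = 0.05), n, 3)

  rec <- list(data = cbind(meg, emg, acc),
              info = channel_info_for(config$n_pairs),
              sfreq = sf,
              events = events,
              trials = data.frame(trial = seq_len(nt), event_sample = events,
                                  accidental_movement = acc_accident,
                                  emg_burst = emg_burst),
              weights = weights, group = group, session = session, seed = seed)
  colnames(rec$data) <- rec$info$name
  class(rec) <- "continuous_recording"
  rec
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("Continuous recording: %d channels x %d samples @ %g Hz, %d events\n",
              ncol(x$data), nrow(x$data), x$sfreq, length(x$events)))
  invisible(x)
}

# subject-level covariate table (seeded once per study from the master seed)
simulate_subject_table <- function(config) {
  set.seed(session_seed(config$seed, 0L, 0L))
  n <- config$n_pd + config$n_hc
  group <- rep(c("pd", "hc"), c(config$n_pd, config$n_hc))
  pd <- group == "pd"
  age <- ifelse(pd, round(stats::runif(n, 44, 75)), round(stats::runif(n, 54, 76)))
  sex <- ifelse(stats::runif(n) < ifelse(pd, 0.25, 0.31), "F", "M")
  updrs_off <- ifelse(pd, pmax(5, stats::rnorm(n, 31, 13.2)),
                      pmax(0, stats::rnorm(n, 1.1, 1.7)))
  updrs_on <- ifelse(pd, pmax(1, updrs_off - stats::rnorm(n, 14.7, 6)), NA)
  data.frame(subject = sprintf("S%02d", seq_len(n)), group = group, age = age,
             sex = sex,
             updrs_off = round(updrs_off, 1), updrs_on = round(updrs_on, 1),
             moca = round(pmin(30, stats::rnorm(n, ifelse(pd, 25.7, 26.1),
                                                ifelse(pd, 3.1, 1.9)))),
             hads_anxiety = round(pmax(0, stats::rnorm(n, ifelse(pd, 4.1, 2.9),
                                                       ifelse(pd, 3.1, 1.7)))),
             hads_depression = round(pmax(0, stats::rnorm(n, ifelse(pd, 2.9, 1.6),
                                                          ifelse(pd, 2.6, 1.0)))),
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic study
#'
#' Generates per-subject, per-session continuous recordings together with a
#' subject covariate table and the ground truth of every injected effect.
#' Identical configurations and seeds yield bit-identical studies. For large
#' configurations (the default is 28 subjects x 2 sessions at 1 kHz) the
#' materialized study is several gigabytes; the analysis pipeline
#' ([extract_study_features()]) therefore streams subject-sessions through
#' [simulate_session()] instead of calling this function.
#'
#' @param config A [sim_config()].
#' @return A `synthetic_study`: list with `recordings` (nested list,
#'   `recordings[[subject]][[session]]`), `subjects` (covariate table),
#'   `ground_truth`, and `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  subjects <- simulate_subject_table(config)
  recordings <- vector("list", nrow(subjects))
  names(recordings) <- subjects$subject
  trials <- list()
  for (i in seq_len(nrow(subjects))) {
    recordings[[i]] <- vector("list", config$n_sessions)
    for (s in seq_len(config$n_sessions)) {
      rec <- simulate_session(config, subjects$group[i], s,
                              session_seed(config$seed, i, s))
      recordings[[i]][[s]] <- rec
      tr <- rec$trials
      tr$subject <- subjects$subject[i]
      tr$session <- s
      trials[[length(trials) + 1]] <- tr
    }
  }
  gt <- list(cells = list(erd_depth = config$erd_depth,
                          rebound_gain = config$rebound_gain,
                          erd_window = config$erd_window,
                          rebound_window = config$rebound_window,
                          carrier_freqs = config$carrier_freqs),
             subjects = subjects[, c("subject", "group")],
             trials = do.call(rbind, trials))
  structure(list(recordings = recordings, subjects = subjects,
                 ground_truth = gt, config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("Synthetic study: %d subjects (%d pd, %d hc), %d session(s), %d trials/session\n",
              nrow(x$subjects), x$config$n_pd, x$config$n_hc,
              x$config$n_sessions, x$config$n_trials))
  invisible(x)
}

#' Simulate subject-level null time-frequency grids
#'
#' Draws per-subject time-frequency grids from a shared Gaussian null (no
#' group or session effect) for calibrating the false-positive rate of the
#' cluster permutation tests on a reduced grid. The time axis includes a
#' pre-stimulus segment so interaction-style re-baselining can be exercised.
#'
#' @param n_subjects Number of subjects.
#' @param n_freqs,n_times Grid size.
#' @param n_sessions Sessions per subject.
#' @param seed RNG seed.
#' @return List with `grids` (array `n_subjects x n_freqs x n_times`, or a
#'   list of such arrays when `n_sessions > 1`), `freqs`, and `times`.
#' @export
simulate_null_grids <- function(n_subjects, n_freqs = 8, n_times = 10,
                                n_sessions = 1, seed = 1L) {
  set.seed(seed)
  freqs <- seq(8, by = 2, length.out = n_freqs)
  times <- seq(-0.4, by = 0.2, length.out = n_times)
  draw <- function() array(stats::rnorm(n_subjects * n_freqs * n_times),
                           dim = c(n_subjects, n_freqs, n_times))
  grids <- if (n_sessions == 1) draw() else lapply(seq_len(n_sessions),
                                                   function(s) draw())
  list(grids = grids, freqs = freqs, times = times)
}
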