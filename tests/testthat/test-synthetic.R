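# Synthetic-data generator: envelope shape, event timing, determinism,
# spectral content, and the injected group effect.

test_that("envelope hits its plateaus and reduces to identity", {
  t <- seq(-1, 3, by = 1e-3)
  env <- make_envelope(t, c(0, 0.5), c(0.5, 1.5), 0.5, 0.8, ramp = 0.1)
  expect_true(all(env[t < 0] == 1))
  expect_true(all(env[t > 1.7] == 1))
  expect_equal(unique(env[t > 0.1 + 1e-9 & t <= 0.5]), 0.5)
  # mean over the rebound plateau
  expect_equal(mean(env[t > 0.6 & t <= 1.5]), 1.8, tolerance = 1e-6)
  expect_true(all(make_envelope(t, c(0, 0.5), c(0.5, 1.5), 0, 0) == 1))
  # transitions are continuous at the sampling resolution (the steepest
  # raised-cosine step is pi * (1.8 - 0.5) / (2 * ramp) per second)
  expect_lt(max(abs(diff(env))), 0.025)
  expect_error(make_envelope(t, c(0, 0.7), c(0.5, 1.5), 0.5, 0.8),
               "overlap")
})

test_that("configuration validation catches impossible settings", {
  expect_error(sim_config(n_pd = 0), "counts")
  expect_error(sim_config(erd_depth = 1.5), "erd_depth")
  expect_error(sim_config(rebound_gain = -0.1), "rebound_gain")
  expect_error(sim_config(iti_range = c(1.0, 1.2)), "timing")
  expect_error(sim_config(evoked_peak = 0.2), "evoked_peak")
})

test_that("sessions have the configured event count and inter-trial timing", {
  cfg <- sim_config(n_pd = 1, n_hc = 1, n_sessions = 1, seed = 2)
  rec <- simulate_session(cfg, "hc", 1, seed = 11)
  expect_equal(length(rec$events), 90)
  itis <- diff(rec$events) / rec$sfreq
  expect_true(all(itis >= 3.5 - 1e-3 & itis <= 4.0 + 1e-3))
  expect_true(all(diff(rec$events) > 0))
  expect_equal(nrow(rec$info), ncol(rec$data))
  # no accidental movements injected by default
  expect_false(any(rec$trials$accidental_movement))
  expect_false(any(rec$trials$emg_burst))
})

test_that("identical seeds give bit-identical output", {
  cfg <- tiny_config()
  r1 <- simulate_session(cfg, "pd", 1, 99)
  r2 <- simulate_session(cfg, "pd", 1, 99)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$events, r2$events)
  s1 <- simulate_study(tiny_config())
  s2 <- simulate_study(tiny_config())
  expect_identical(s1$recordings[[1]][[1]]$data, s2$recordings[[1]][[1]]$data)
  expect_identical(s1$subjects, s2$subjects)
})

test_that("noise-free baseline spectrum peaks at the carrier frequencies", {
  cfg <- tiny_config(noise_amp = 0, evoked_amp = 0)
  rec <- simulate_session(cfg, "hc", 1, 5)
  # baseline segment: 1 s before the third event on one pair member
  seg <- rec$data[(rec$events[3] - 1000):(rec$events[3] - 1), 1]
  n <- length(seg)
  p <- Mod(stats::fft(seg))[1:(n / 2)] ^ 2
  f <- (0:(n / 2 - 1)) * rec$sfreq / n
  pks <- order(p, decreasing = TRUE)[1:2]
  expect_setequal(round(f[pks]), c(10, 20))
})

test_that("a stationary configuration yields time-constant variance", {
  cfg <- tiny_config(noise_amp = 0, evoked_amp = 0, erd_depth = 0,
                     rebound_gain = 0)
  set.seed(1)
  sig <- simulate_trial_signal(cfg, "pd", 1, window = c(-1, 2))
  tt <- attr(sig, "times")
  v1 <- apply(sig[, tt < 0], 1, var)
  v2 <- apply(sig[, tt >= 0.6 & tt <= 1.4], 1, var)
  expect_equal(v1, v2, tolerance = 0.05)
})

test_that("band amplitude rises monotonically with the rebound gain", {
  amps <- vapply(c(0, 0.4, 0.8, 1.2), function(g) {
    cfg <- tiny_config(noise_amp = 0, evoked_amp = 0,
                       rebound_gain = g)
    set.seed(3)
    sig <- simulate_trial_signal(cfg, "pd", 1, window = c(-1, 2))
    tt <- attr(sig, "times")
    amp <- band_amplitude(sig[1, ], cfg$sfreq, c(15, 25))
    mean(amp[tt > 0.7 & tt < 1.4])
  }, numeric(1))
  expect_true(all(diff(amps) > 0))
})

test_that("patient trials show a weaker rebound than control trials", {
  cfg <- sim_config(n_pd = 1, n_hc = 1, n_sessions = 1, n_trials = 1,
                    n_pairs = 1, seed = 1)
  set.seed(42)
  n_draws <- 200
  wins <- logical(n_draws)
  for (i in seq_len(n_draws)) {
    w <- rep(0.7, 2)
    hc <- simulate_trial_signal(cfg, "hc", 1, window = c(-0.5, 2), weights = w)
    pd <- simulate_trial_signal(cfg, "pd", 1, window = c(-0.5, 2), weights = w)
    tt <- attr(hc, "times")
    sel <- tt > 0.7 & tt < 1.4
    a_hc <- mean(band_amplitude(hc[1, ], cfg$sfreq, c(15, 25))[sel])
    a_pd <- mean(band_amplitude(pd[1, ], cfg$sfreq, c(15, 25))[sel])
    wins[i] <- a_hc > a_pd
  }
  expect_gte(mean(wins), 0.95)
})

test_that("oscillations cancel in the average while the evoked transient survives", {
  cfg <- sim_config(n_pd = 1, n_hc = 1, n_sessions = 1, n_trials = 60,
                    n_pairs = 1, noise_amp = 0, seed = 9)
  rec <- simulate_session(cfg, "hc", 1, 21)
  ep <- epoch_continuous(rec, -0.5, 1.5,
                         channels = which(rec$info$type == "grad"))
  evoked <- colMeans(ep$data[, 1, ])
  tt <- ep$times
  # oscillatory baseline averages toward zero (carrier amplitude is
  # weights * baseline_amp ~ 0.3-1 * 20 per carrier)
  expect_lt(max(abs(evoked[tt < -0.1])), 0.25 * 20)
  # the phase-locked transient stands out at its programmed latency
  expect_gt(max(evoked[tt > 0.05 & tt < 0.11]), 5)
})

test_that("accidental movements and EMG bursts are recorded in the ground truth", {
  cfg <- tiny_config(acc_movement_prob = 1, emg_burst_prob = 0.5)
  rec <- simulate_session(cfg, "pd", 1, 13)
  expect_true(all(rec$trials$accidental_movement))
  expect_true(any(rec$trials$emg_burst) && !all(rec$trials$emg_burst))
  study <- simulate_study(cfg)
  expect_equal(nrow(study$ground_truth$trials),
               4 * cfg$n_trials * cfg$n_sessions)
})

test_that("shaped noise follows the configured spectral slope", {
  set.seed(4)
  x <- pink_noise(2 ^ 16, 1, sfreq = 1000, exponent = 1)
  sp <- stats::spec.pgram(stats::ts(x[, 1], frequency = 1000), spans = 101,
                          plot = FALSE)
  sel <- sp$freq > 2 & sp$freq < 150
  slope <- unname(coef(lm(log10(sp$spec[sel]) ~ log10(sp$freq[sel])))[2])
  expect_lt(abs(slope - (-1)), 0.3)
  expect_equal(sd(x), 1, tolerance = 0.01)
})
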