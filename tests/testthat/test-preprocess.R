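# Epoching, rejection rules, induced-response extraction, and side-channel
# conditioning.

test_that("epoching yields inclusive windows and logs edge events", {
  set.seed(1)
  rec <- list(data = matrix(rnorm(20000 * 2), ncol = 2),
              info = data.frame(name = c("a", "b"), type = "grad",
                                pair = c(1, 1), unit = "au"),
              sfreq = 1000, events = c(100L, 5000L, 9000L, 19900L))
  ep <- epoch_continuous(rec, -1.5, 3.5)
  expect_equal(dim(ep$data)[3], 5001)
  # events at samples 100 (insufficient history) and 19900 (insufficient
  # future) are skipped and logged
  expect_equal(ep$trial_ids, c(2L, 3L))
  expect_equal(ep$rejection_log$reason, c("edge", "", "", "edge"))
  expect_equal(nrow(ep$rejection_log), 4)
  # samples come straight from the recording
  expect_equal(ep$data[1, 1, ], rec$data[3500:8500, 1])
  expect_equal(ep$times[1], -1.5)
  expect_equal(ep$times[5001], 3.5)
})

test_that("non-overlapping epochs reconstruct the original recording", {
  set.seed(2)
  rec <- list(data = matrix(rnorm(6000), ncol = 1),
              info = data.frame(name = "a", type = "grad", pair = 1,
                                unit = "au"),
              sfreq = 1000, events = c(1000L, 3000L, 5000L))
  ep <- epoch_continuous(rec, 0, 0.999)
  recon <- c(t(ep$data[, 1, ]))
  orig <- c(rec$data[1000:1999, 1], rec$data[3000:3999, 1],
            rec$data[5000:5999, 1])
  expect_identical(recon, orig)
})

test_that("peak-to-peak rejection is strict, typed, and idempotent", {
  d <- array(0, dim = c(3, 2, 100))
  d[2, 1, 50] <- 2500      # gradiometer range 2500 > 2000 -> reject
  d[3, 2, 10] <- 1000      # range exactly 2000 stays
  d[3, 2, 11] <- -1000
  ep <- mk_epochs(d)
  out <- reject_amplitude_jumps(ep, ptp_thresholds())
  expect_equal(dim(out$data)[1], 2)
  expect_equal(out$rejection_log$reason[2], "ptp")
  expect_true(out$rejection_log$kept[3])   # boundary equality keeps
  expect_true(out$rejection_log$kept[1])   # all-zero epoch keeps
  # idempotence
  again <- reject_amplitude_jumps(out, ptp_thresholds())
  expect_equal(dim(again$data)[1], 2)
  expect_equal(again$rejection_log, out$rejection_log)
  # unknown channel type is a configuration error
  ep2 <- mk_epochs(d, types = c("grad", "weird"))
  expect_error(reject_amplitude_jumps(ep2, ptp_thresholds()), "weird")
  # magnetometer threshold applies to mag channels
  d3 <- array(0, dim = c(1, 1, 10)); d3[1, 1, 5] <- 2e4
  expect_equal(dim(reject_amplitude_jumps(mk_epochs(d3, types = "mag"),
                                          ptp_thresholds())$data)[1], 0)
})

test_that("accelerometer norm is z-scored and tracks the stimulus", {
  cfg <- tiny_config()
  rec <- simulate_session(cfg, "hc", 1, 3)
  acc <- rec$data[, rec$info$type == "acc"]
  nrm <- accelerometer_norm(acc, rec$sfreq)
  expect_equal(mean(nrm), 0, tolerance = 1e-9)
  expect_equal(sd(nrm), 1, tolerance = 1e-9)
  # the norm peaks within the stimulus window of each event
  for (ev in rec$events[1:3]) {
    seg <- nrm[ev:(ev + 500)]
    expect_gt(max(abs(seg)), 3)
  }
  expect_error(accelerometer_norm(matrix(0, 100, 2), 1000), "3 axes")
  expect_error(accelerometer_norm(matrix(0, 100, 3), 300), "sfreq")
})

test_that("movement flagging respects the stimulus window", {
  times <- seq(-1.5, 3.5, by = 1e-3)
  flat <- matrix(0, 1, length(times))
  inside <- flat; inside[1, times > 0.1 & times < 0.4] <- 6
  outside <- flat; outside[1, times > 1.2 & times < 1.5] <- 6
  short <- flat; short[1, which(times > 1.2)[1:5]] <- 6  # 5 ms < min_dur
  x <- rbind(flat, inside, outside, short)
  flags <- flag_accidental_movements(x, times)
  expect_equal(flags, c(FALSE, FALSE, TRUE, FALSE))
  expect_error(flag_accidental_movements(x, times, window = c(0, 4)),
               "window")
})

test_that("flagging recovers the injected accidental movements", {
  cfg <- tiny_config(acc_movement_prob = 0.5)
  rec <- simulate_session(cfg, "pd", 1, 8)
  nrm <- accelerometer_norm(rec$data[, rec$info$type == "acc"], rec$sfreq)
  acc_rec <- list(data = matrix(nrm, ncol = 1), info = rec$info[23, ],
                  sfreq = rec$sfreq, events = rec$events)
  ep <- epoch_continuous(acc_rec, -1.5, 2.0)
  flags <- flag_accidental_movements(ep$data[, 1, ], ep$times)
  injected <- rec$trials$accidental_movement[ep$trial_ids]
  expect_true(any(injected))
  # every injected movement is caught (neighbouring trials may also be
  # flagged when a transient falls into their epoch window)
  expect_true(all(flags[injected]))
})

test_that("evoked subtraction removes phase-locked but keeps induced power", {
  # identical trials -> all zero, and the output mean is exactly zero
  d <- array(rep(sin(2 * pi * 20 * seq(0, 1, 1e-3)), each = 4),
             dim = c(4, 1, 1001))
  out <- subtract_evoked(mk_epochs(d))
  expect_lt(max(abs(out$data)), 1e-12)
  set.seed(3)
  d2 <- array(rnorm(4 * 1 * 1001), dim = c(4, 1, 1001))
  out2 <- subtract_evoked(mk_epochs(d2))
  expect_lt(max(abs(colMeans(out2$data, dims = 1))), 1e-12)
  expect_error(subtract_evoked(mk_epochs(d2[1, , , drop = FALSE])),
               "2 kept trials")
})

test_that("rejection log always covers every original trial", {
  cfg <- tiny_config(acc_movement_prob = 0.3)
  rec <- simulate_session(cfg, "pd", 1, 77)
  ep <- epoch_continuous(rec, -1.5, 2.0,
                         channels = which(rec$info$type == "grad"))
  ep <- reject_amplitude_jumps(ep, ptp_thresholds(grad_ptp = 150))
  expect_equal(nrow(ep$rejection_log), cfg$n_trials)
  expect_equal(sum(ep$rejection_log$kept), dim(ep$data)[1])
  expect_true(all(ep$rejection_log$reason[!ep$rejection_log$kept] != ""))
})

test_that("EMG conditioning notches the line, rectifies, and localizes the PSD", {
  sf <- 1000
  t <- seq(0, 2, by = 1 / sf)
  line <- matrix(sin(2 * pi * 50 * t), 1)
  out <- preprocess_emg(line, sf)
  mid <- 400:1600
  atten <- 20 * log10(sqrt(mean(line[1, mid] ^ 2)) /
                        sqrt(mean((abs(out$rectified[1, mid])) ^ 2)))
  expect_gt(atten, 40)
  tone <- matrix(sin(2 * pi * 20 * t), 1)
  out2 <- preprocess_emg(tone, sf)
  expect_equal(out2$psd$freq[which.max(out2$psd$power)], 20, tolerance = 0.3)
  expect_true(all(out2$rectified >= 0))
  expect_equal(out2$average, colMeans(out2$rectified))
})
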