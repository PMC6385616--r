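# Morlet decomposition, pair combination, peak-pair selection, and
# log-baseline correction.

sf <- 1000
tt <- seq(-1.5, 3.5, by = 1 / sf)

test_that("zero input gives zero power and silly configs error", {
  ep <- mk_epochs(matrix(0, 1, length(tt)))
  tfr <- morlet_tfr(ep, freqs = c(10, 20))
  expect_true(all(tfr$power[!is.na(tfr$power)] == 0))
  expect_error(morlet_tfr(ep, width = 0), "width")
  expect_error(morlet_tfr(ep, freqs = numeric(0)), "empty")
})

test_that("a stationary sinusoid is recovered at its carrier with flat power", {
  ep <- mk_epochs(matrix(sin(2 * pi * 10 * tt), 1))
  tfr <- morlet_tfr(ep)
  interior <- tfr$times > -0.5 & tfr$times < 2
  pw <- tfr$power[1, , interior]
  expect_true(all(tfr$freqs[apply(pw, 2, which.max)] == 10))
  p10 <- pw[tfr$freqs == 10, ]
  expect_lt(diff(range(p10)) / mean(p10), 0.01)
  expect_equal(mean(p10), 1, tolerance = 0.01)   # unit amplitude -> power 1
  # quadratic amplitude scaling at every bin
  ep2 <- mk_epochs(matrix(2 * sin(2 * pi * 10 * tt), 1))
  tfr2 <- morlet_tfr(ep2)
  r <- tfr2$power / tfr$power
  expect_equal(range(r, na.rm = TRUE), c(4, 4), tolerance = 1e-9)
})

test_that("edge bins without full wavelet support are missing", {
  ep <- mk_epochs(matrix(1 + sin(2 * pi * 10 * tt), 1))
  tfr <- morlet_tfr(ep, freqs = c(8, 20))
  # at 8 Hz, 3 temporal SDs = 0.30 s: the first output bin (-1.25 s) has
  # only 0.25 s of history and must be NA; at 20 Hz it is valid
  expect_true(is.na(tfr$power[1, 1, 1]))
  expect_false(is.na(tfr$power[1, 2, 1]))
})

test_that("impulse response width matches the analytic wavelet envelope", {
  imp <- numeric(length(tt)); imp[which.min(abs(tt - 1))] <- 1
  tfr <- morlet_tfr(mk_epochs(matrix(imp, 1)), freqs = 20,
                    times = seq(0, 2, by = 0.005))
  amp <- sqrt(tfr$power[1, 1, ])
  w <- amp / sum(amp)
  mu <- sum(w * tfr$times)
  sdt <- sqrt(sum(w * (tfr$times - mu) ^ 2))
  expect_equal(sdt, 5 / (2 * pi * 20), tolerance = 0.1)
})

test_that("pair combination is Pythagorean, monotone, and order-invariant", {
  expect_equal(as.vector(combine_pairs(c(3, 4))), 5)
  expect_equal(as.vector(combine_pairs(c(9, 16), domain = "power")), 25)
  expect_equal(as.vector(combine_pairs(c(0, 7))), 7)
  expect_equal(combine_pairs(c(4, 3)), combine_pairs(c(3, 4)))
  expect_gt(combine_pairs(c(3.5, 4)), combine_pairs(c(3, 4)))
  m <- matrix(c(3, 4, 1, 2), nrow = 4)       # two pairs, one sample
  expect_equal(as.vector(combine_pairs(m)), c(5, sqrt(5)))
  expect_error(combine_pairs(matrix(1, 3, 2)), "unpaired")
})

test_that("peak-pair selection finds the construction and logs ties", {
  ns <- length(tt)
  bump <- exp(-(tt - 0.08) ^ 2 / (2 * 0.02 ^ 2))
  d <- array(0, dim = c(6, 6, ns))           # 6 trials x 3 pairs
  for (k in 1:6) {
    d[k, 3, ] <- 40 * bump                    # pair 2, member A
    d[k, 4, ] <- 30 * bump                    # pair 2, member B
    d[k, 1, ] <- 10 * bump
  }
  ep <- mk_epochs(d)
  sel <- select_peak_pair(ep)
  expect_equal(sel$pair, 2)
  expect_false(sel$tie)
  expect_equal(sel$window, c(0.05, 0.11))
  # identical signals on every pair: lowest index wins and the tie is logged
  d2 <- array(rep(bump, each = 6 * 4), dim = c(6, 4, ns))
  sel2 <- select_peak_pair(mk_epochs(d2))
  expect_equal(sel2$pair, 1)
  expect_true(sel2$tie)
  expect_error(select_peak_pair(ep, window = c(0.11, 0.05)), "window")
})

test_that("log-baseline correction obeys its identities", {
  freqs <- 8:12
  times <- seq(-1.25, 2.5, by = 0.25)
  pw <- array(2, dim = c(1, length(freqs), length(times)))
  tfr <- structure(list(power = pw, freqs = freqs, times = times,
                        state = "raw-power", baseline_window = NULL),
                   class = "tfr_grid")
  out <- baseline_log_correct(tfr)
  expect_lt(max(abs(out$power)), 1e-12)       # constant power -> 0
  expect_equal(out$state, "baseline-corrected")
  # 10x the baseline level maps to +1.0
  pw2 <- pw; pw2[1, , times > 0] <- 20
  tfr2 <- structure(list(power = pw2, freqs = freqs, times = times,
                         state = "raw-power", baseline_window = NULL),
                    class = "tfr_grid")
  out2 <- baseline_log_correct(tfr2)
  expect_equal(unique(as.vector(out2$power[1, , times > 0])), 1)
  # per-frequency baseline mean is zero; invariant to global rescaling
  set.seed(5)
  pw3 <- array(rexp(1 * 5 * 16), dim = c(1, 5, 16))
  tfr3 <- structure(list(power = pw3, freqs = freqs, times = times,
                         state = "raw-power", baseline_window = NULL),
                    class = "tfr_grid")
  out3 <- baseline_log_correct(tfr3)
  bsel <- times >= -1.25 & times <= -0.2
  expect_lt(max(abs(rowMeans(out3$power[1, , bsel]))), 1e-9)
  tfr3b <- tfr3; tfr3b$power <- tfr3$power * 37.5
  expect_equal(baseline_log_correct(tfr3b)$power, out3$power)
  # non-positive bins error unless floored
  tfr4 <- tfr3; tfr4$power[1, 1, 1] <- 0
  expect_error(baseline_log_correct(tfr4), "floor")
  expect_silent(baseline_log_correct(tfr4, floor = 1e-30))
  expect_error(baseline_log_correct(out3), "raw-power")
})

test_that("band extraction keeps the inclusive frequency rows", {
  pw <- array(1, dim = c(1, 39, 4))
  tfr <- structure(list(power = pw, freqs = 2:40, times = 1:4 / 10,
                        state = "raw-power", baseline_window = NULL),
                   class = "tfr_grid")
  expect_equal(length(extract_band(tfr, c(8, 30))$freqs), 23)
  expect_equal(length(extract_band(tfr, c(14, 25))$freqs), 12)
  expect_equal(extract_band(tfr, c(2, 40))$freqs, 2:40)
  expect_error(extract_band(tfr, c(45, 50)), "empty band")
})
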