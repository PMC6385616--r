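# Morlet-wavelet time-frequency decomposition, planar-pair combination,
# peak-channel selection, and log-baseline correction.

new_tfr_grid <- function(power, freqs, times, state, baseline_window = NULL) {
  structure(list(power = power, freqs = freqs, times = times, state = state,
                 baseline_window = baseline_window),
            class = "tfr_grid")
}

#' @export
print.tfr_grid <- function(x, ...) {
  cat(sprintf("TFR grid [%s]: %d unit(s) x %d freqs (%g-%g Hz) x %d times (%.2f to %.2f s)\n",
              x$state, dim(x$power)[1], length(x$freqs), min(x$freqs),
              max(x$freqs), length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
plot.tfr_grid <- function(x, unit = 1, ...) {
  z <- t(x$power[unit, , ])
  graphics::image(x$times, x$freqs, z, xlab = "time (s)",
                  ylab = "frequency (Hz)",
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE), ...)
  invisible(x)
}

#' Morlet-wavelet time-frequency decomposition
#'
#' Convolves every trial and channel with complex Morlet wavelets of fixed
#' cycle number (`width` cycles: temporal SD `width / (2 pi f)`) and returns
#' power (squared coefficient magnitude), averaged across trials by default.
#' Coefficients are evaluated in the frequency domain, so arbitrary output
#' time grids are supported. The wavelet is scaled so a unit-amplitude
#' sinusoid at a grid frequency yields power 1 at its carrier.
#'
#' Output bins whose wavelet support (3 temporal SDs either side) extends
#' beyond the epoch are set to `NA` rather than zero-padded; downstream
#' statistics ignore such bins.
#'
#' @param epochs An `epochs_set` (all channels are decomposed).
#' @param freqs Analysis frequencies in Hz (default 2--40 in 1 Hz steps).
#' @param width Wavelet width in cycles (default 5).
#' @param times Output time grid in seconds (default -1.25 to 2.5 in 50 ms
#'   steps).
#' @param average Average power across trials (default `TRUE`).
#' @return A `tfr_grid` with `power` of dimension `channels x freqs x times`
#'   (state `"raw-power"`), or `trials x channels x freqs x times` when
#'   `average = FALSE`.
#' @export
morlet_tfr <- function(epochs, freqs = 2:40, width = 5,
                       times = seq(-1.25, 2.5, by = 0.05), average = TRUE) {
  if (width <= 0) stop("wavelet width must be > 0")
  if (length(freqs) == 0) stop("empty frequency list")
  if (any(freqs <= 0)) stop("frequencies must be > 0")
  sf <- epochs$sfreq
  dims <- dim(epochs$data)
  nt <- dims[1]; nc <- dims[2]; ns <- dims[3]
  t0 <- epochs$times[1]
  sigma_t <- width / (2 * pi * freqs)
  pad <- ceiling(2 * 3 * max(sigma_t) * sf)
  nfft <- as.integer(sf * ceiling((ns + pad) / sf))
  # flatten trials x channels into columns, zero-padded
  x <- matrix(0, nfft, nt * nc)
  x[seq_len(ns), ] <- t(matrix(epochs$data, nt * nc, ns))
  X <- stats::mvfft(x)
  fbin <- (seq_len(nfft) - 1) * sf / nfft     # DFT bin frequencies (one-sided use)
  out <- array(NA_real_, dim = c(nt, nc, length(freqs), length(times)))
  valid_t <- outer(sigma_t, times, function(s, tt)
    tt - t0 >= 3 * s & (epochs$times[ns] - tt) >= 3 * s)
  for (j in seq_along(freqs)) {
    f <- freqs[j]
    sigma_f <- 1 / (2 * pi * sigma_t[j])
    sel <- which(fbin <= sf / 2 & abs(fbin - f) <= 5 * sigma_f)
    if (length(sel) == 0) next
    w <- exp(-(fbin[sel] - f) ^ 2 / (2 * sigma_f ^ 2))
    # inverse DFT restricted to the wavelet's support, evaluated at the
    # requested output times (analytic: positive frequencies only, x2)
    E <- exp(2i * pi * outer(times - t0, fbin[sel])) *
      rep(w, each = length(times))
    coef <- (2 / nfft) * (E %*% X[sel, , drop = FALSE])
    pw <- Mod(coef) ^ 2                        # times x (trials*channels)
    pw[!valid_t[j, ], ] <- NA_real_
    out[, , j, ] <- aperm(array(pw, dim = c(length(times), nt, nc)), c(2, 3, 1))
  }
  if (average) {
    avg <- colMeans(out, dims = 1)             # channels x freqs x times
    new_tfr_grid(avg, freqs, times, "raw-power")
  } else {
    new_tfr_grid(out, freqs, times, "raw-power")
  }
}

#' Combine orthogonal channel pairs
#'
#' Collapses the two members of each orthogonal planar-gradiometer-like pair
#' into a single orientation-invariant value: root-sum-of-squares for
#' amplitude-domain inputs, or the sum of the two powers (equivalent to the
#' RSS of amplitudes) for power-domain inputs.
#'
#' @param x Per-channel values: a matrix `channels x ...` or an array whose
#'   first dimension indexes channels, ordered so channels `2k - 1` and `2k`
#'   form pair `k`, or with an explicit `pairs` grouping.
#' @param domain `"amplitude"` (RSS) or `"power"` (sum).
#' @param pairs Integer vector assigning each channel to a pair (default:
#'   consecutive channels form pairs).
#' @return The combined array with one entry per pair in the first
#'   dimension.
#' @export
combine_pairs <- function(x, domain = c("amplitude", "power"), pairs = NULL) {
  domain <- match.arg(domain)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  d <- dim(x)
  nch <- d[1]
  if (is.null(pairs)) {
    if (nch %% 2 != 0) stop("odd channel count: unpaired channel")
    pairs <- rep(seq_len(nch / 2), each = 2)
  }
  if (length(pairs) != nch) stop("pairs must assign every channel")
  if (any(table(pairs) != 2)) stop("every pair must have exactly 2 members")
  up <- sort(unique(pairs))
  flat <- matrix(x, nrow = nch)
  pw <- if (domain == "amplitude") flat ^ 2 else flat
  comb <- rowsum(pw, pairs)[as.character(up), , drop = FALSE]
  if (domain == "amplitude") comb <- sqrt(comb)
  array(comb, dim = c(length(up), d[-1]))
}

#' Select the channel pair with the strongest early evoked response
#'
#' Averages all kept trials across the supplied sessions (the phase-locked
#' evoked response), low-pass filters it, combines channel pairs by RSS
#' amplitude, and returns the pair whose mean combined amplitude within the
#' selection window (default 50--110 ms post-stimulus) is highest. Ties are
#' broken toward the lowest pair index and flagged.
#'
#' @param epochs_list A list of `epochs_set` objects (e.g. one per session)
#'   restricted to gradiometer channels.
#' @param window Selection window in seconds (default `c(0.05, 0.11)`).
#' @param lp Low-pass corner in Hz applied to the evoked average (default
#'   90; `NULL` to skip).
#' @return List with `pair` (selected pair index), `score`, `scores` (per
#'   pair), `window`, and `tie` (logical).
#' @export
select_peak_pair <- function(epochs_list, window = c(0.05, 0.11), lp = 90) {
  if (inherits(epochs_list, "epochs_set")) epochs_list <- list(epochs_list)
  if (window[2] <= window[1]) stop("empty selection window")
  sums <- NULL
  ntot <- 0
  for (ep in epochs_list) {
    s <- colSums(ep$data, dims = 1)
    sums <- if (is.null(sums)) s else sums + s
    ntot <- ntot + dim(ep$data)[1]
  }
  evoked <- sums / ntot                        # channels x samples
  sf <- epochs_list[[1]]$sfreq
  times <- epochs_list[[1]]$times
  if (!is.null(lp)) {
    flt <- signal::butter(4, lp / (sf / 2), type = "low")
    evoked <- t(apply(evoked, 1, zp_filter, flt = flt))
  }
  comb <- combine_pairs(evoked, domain = "amplitude",
                        pairs = epochs_list[[1]]$info$pair)
  sel <- times >= window[1] & times <= window[2]
  scores <- rowMeans(comb[, sel, drop = FALSE])
  best <- which(scores == max(scores))
  tie <- length(best) > 1
  list(pair = best[1], score = max(scores), scores = scores,
       window = window, tie = tie)
}

#' Log-transform and baseline-correct a time-frequency grid
#'
#' Applies `log10` to raw power and subtracts, per frequency (and unit),
#' the mean log power over the baseline window. The corrected grid has
#' per-frequency baseline mean zero; missing (edge) bins are ignored.
#'
#' @param tfr A `tfr_grid` in state `"raw-power"`.
#' @param baseline Baseline window in seconds (default `c(-1.25, -0.2)`).
#' @param floor Optional positive floor applied to power before the log;
#'   without it, non-positive power is an error.
#' @return The corrected `tfr_grid` (state `"baseline-corrected"`).
#' @export
baseline_log_correct <- function(tfr, baseline = c(-1.25, -0.2), floor = NULL) {
  if (tfr$state != "raw-power")
    stop("baseline_log_correct expects a raw-power grid")
  if (baseline[1] < min(tfr$times) - 1e-9 || baseline[2] > max(tfr$times) + 1e-9)
    stop("baseline window must lie within the grid times")
  p <- tfr$power
  if (!is.null(floor)) p <- pmax(p, floor)
  if (any(p <= 0, na.rm = TRUE))
    stop("non-positive power bins; supply a positive `floor` to clip them before the log transform")
  lp <- log10(p)
  bsel <- tfr$times >= baseline[1] & tfr$times <= baseline[2]
  nd <- length(dim(lp))
  if (nd == 2) {
    base <- rowMeans(lp[, bsel, drop = FALSE], na.rm = TRUE)
    out <- lp - base
  } else {
    base <- apply(lp[, , bsel, drop = FALSE], c(1, 2), mean, na.rm = TRUE)
    out <- sweep(lp, c(1, 2), base, "-")
  }
  g <- new_tfr_grid(out, tfr$freqs, tfr$times, "baseline-corrected", baseline)
  g
}

#' Restrict a time-frequency grid to a frequency band
#'
#' @param tfr A `tfr_grid`.
#' @param band Two-element band in Hz, endpoints inclusive (default
#'   `c(8, 30)`, the mu/beta range).
#' @return The band-restricted `tfr_grid`.
#' @export
extract_band <- function(tfr, band = c(8, 30)) {
  sel <- tfr$freqs >= band[1] & tfr$freqs <= band[2]
  if (!any(sel)) stop("empty band: no grid frequencies inside it")
  nd <- length(dim(tfr$power))
  power <- if (nd == 2) tfr$power[sel, , drop = FALSE]
           else tfr$power[, sel, , drop = FALSE]
  new_tfr_grid(power, tfr$freqs[sel], tfr$times, tfr$state,
               tfr$baseline_window)
}
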