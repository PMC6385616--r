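# Epoching, artifact rejection, and induced-response extraction.

#' Cut a continuous recording into event-locked epochs
#'
#' Extracts one epoch per event spanning `[tmin, tmax]` seconds around the
#' event sample (closed interval, sampled inclusively: an epoch holds
#' `round((tmax - tmin) * sfreq) + 1` samples). Events too close to a
#' recording edge are skipped and logged, not an error.
#'
#' @param rec A `continuous_recording` (or any list with `data`, `sfreq`,
#'   `events`, `info`).
#' @param tmin,tmax Epoch window in seconds relative to each event
#'   (defaults -1.5 and 3.5).
#' @param channels Optional character vector or indices restricting the
#'   channels kept in the epochs.
#' @return An `epochs_set`: list with `data` (array `trials x channels x
#'   samples`), `times`, `tmin`, `sfreq`, `info`, `trial_ids` (event numbers
#'   of the kept trials), and `rejection_log` (one row per original event).
#' @export
epoch_continuous <- function(rec, tmin = -1.5, tmax = 3.5, channels = NULL) {
  sf <- rec$sfreq
  n <- nrow(rec$data)
  ch <- seq_len(ncol(rec$data))
  info <- rec$info
  if (!is.null(channels)) {
    ch <- if (is.character(channels)) match(channels, info$name) else channels
    info <- info[ch, , drop = FALSE]
  }
  i0 <- as.integer(round(tmin * sf))
  i1 <- as.integer(round(tmax * sf))
  ns <- i1 - i0 + 1L
  ok <- rec$events + i0 >= 1L & rec$events + i1 <= n
  kept <- which(ok)
  data <- cpp_epoch_grab(rec$data, rec$events[kept], i0, ns,
                         as.integer(ch))
  log <- data.frame(trial = seq_along(rec$events),
                    kept = ok,
                    reason = ifelse(ok, "", "edge"),
                    stringsAsFactors = FALSE)
  structure(list(data = data, times = seq(tmin, by = 1 / sf, length.out = ns),
                 tmin = tmin, sfreq = sf, info = info,
                 trial_ids = kept, rejection_log = log),
            class = "epochs_set")
}

#' @export
print.epochs_set <- function(x, ...) {
  cat(sprintf("Epochs: %d kept trials x %d channels x %d samples (%.2f to %.2f s), %d rejected\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$times), max(x$times), sum(!x$rejection_log$kept)))
  invisible(x)
}

# remove trials from an epochs_set, appending the reason to the log
drop_trials <- function(epochs, drop_idx, reason) {
  if (length(drop_idx) == 0) return(epochs)
  orig <- epochs$trial_ids[drop_idx]
  epochs$rejection_log$kept[orig] <- FALSE
  epochs$rejection_log$reason[orig] <- reason
  epochs$data <- epochs$data[-drop_idx, , , drop = FALSE]
  epochs$trial_ids <- epochs$trial_ids[-drop_idx]
  epochs
}

#' Peak-to-peak rejection thresholds per channel type
#'
#' Thresholds on the within-epoch min-to-max range, one per channel type.
#' The defaults correspond to 10 pT for magnetometers (expressed in fT) and
#' 2000 fT/cm for planar gradiometers, the conventional jump-artifact limits
#' for these sensor types.
#'
#' @param grad_ptp Gradiometer threshold (fT/cm).
#' @param mag_ptp Magnetometer threshold (fT; 10 pT = 1e4 fT).
#' @param ... Further named `type = threshold` entries (e.g. `emg = Inf`).
#' @return Named numeric vector of thresholds.
#' @export
ptp_thresholds <- function(grad_ptp = 2000, mag_ptp = 1e4, ...) {
  thr <- c(grad = grad_ptp, mag = mag_ptp, ...)
  if (any(thr <= 0)) stop("thresholds must be > 0")
  thr
}

#' Reject trials with extreme amplitude jumps
#'
#' A trial is rejected iff any channel's min-to-max peak range strictly
#' exceeds the threshold for its channel type; range exactly equal to the
#' threshold keeps the trial. Rejected trials are logged with reason
#' `"ptp"`. Re-applying the same thresholds to the kept trials rejects
#' nothing (idempotence).
#'
#' @param epochs An `epochs_set`.
#' @param thr Named thresholds from [ptp_thresholds()]. Channel types
#'   without an entry are an error.
#' @return The filtered `epochs_set`.
#' @export
reject_amplitude_jumps <- function(epochs, thr = ptp_thresholds()) {
  types <- unique(epochs$info$type)
  missing <- setdiff(types, names(thr))
  if (length(missing))
    stop("no peak-to-peak threshold configured for channel type(s): ",
         paste(missing, collapse = ", "))
  nt <- dim(epochs$data)[1]
  if (nt == 0) return(epochs)
  d <- dim(epochs$data)
  ptp <- cpp_ptp(epochs$data, d[1], d[2], d[3])
  lim <- rep(unname(thr[epochs$info$type]), each = nt)
  bad <- rowSums(ptp > lim) > 0
  drop_trials(epochs, which(bad), "ptp")
}

#' Subtract the evoked (phase-locked) response from every trial
#'
#' Removes the across-trial average per channel and sample from each kept
#' trial, leaving the induced (non-phase-locked) activity. The across-trial
#' mean of the output is zero by construction.
#'
#' @param epochs An `epochs_set` with at least 2 kept trials.
#' @return The demeaned `epochs_set`; the removed average is attached as
#'   attribute `"evoked"` (channels x samples).
#' @export
subtract_evoked <- function(epochs) {
  nt <- dim(epochs$data)[1]
  if (nt < 2)
    stop("evoked subtraction needs at least 2 kept trials")
  evoked <- colMeans(epochs$data, dims = 1)
  epochs$data <- sweep(epochs$data, c(2, 3), evoked, "-")
  attr(epochs, "evoked") <- evoked
  epochs
}
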