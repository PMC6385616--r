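#' Event-locked amplitude envelope with ERD and rebound plateaus
#'
#' Builds the amplitude multiplier applied to the carrier oscillations around
#' one event: the multiplier is 1 in the baseline, dips to `1 - erd_depth`
#' during the ERD window, rises to `1 + rebound_gain` during the rebound
#' window, and returns to 1 afterwards. Transitions are raised-cosine ramps
#' of duration `ramp` starting at each window onset, so the plateau occupies
#' `[start + ramp, end]` of each window.
#'
#' @param times Numeric vector of times in seconds (monotone increasing),
#'   relative to the event at `t = 0`.
#' @param erd_window,rebound_window Two-element windows in seconds; must not
#'   overlap and the ERD window must precede the rebound window.
#' @param erd_depth Fractional suppression in `[0, 1]`.
#' @param rebound_gain Fractional gain `>= 0`.
#' @param ramp Transition duration in seconds (`> 0`).
#'
#' @return Numeric vector of amplitude multipliers, same length as `times`.
#' @examples
#' t <- seq(-1, 3, by = 0.001)
#' env <- make_envelope(t, c(0, 0.5), c(0.5, 1.5), 0.5, 0.8)
#' range(env)
#' @export
make_envelope <- function(times, erd_window = c(0, 0.5),
                          rebound_window = c(0.5, 1.5),
                          erd_depth = 0.5, rebound_gain = 0.8, ramp = 0.1) {
  if (is.unsorted(times)) stop("times must be monotone increasing")
  if (ramp <= 0) stop("ramp must be > 0")
  if (erd_window[2] > rebound_window[1])
    stop("invalid envelope config: erd_window must precede and not overlap rebound_window")
  lo <- 1 - erd_depth
  hi <- 1 + rebound_gain
  # piecewise control points: (time, level) with raised-cosine interpolation
  # between consecutive points over `ramp` seconds
  knots <- rbind(c(erd_window[1], 1), c(erd_window[1] + ramp, lo),
                 c(rebound_window[1], lo), c(rebound_window[1] + ramp, hi),
                 c(rebound_window[2], hi), c(rebound_window[2] + ramp, 1))
  env <- rep(1, length(times))
  for (k in seq_len(nrow(knots) - 1)) {
    t0 <- knots[k, 1]; v0 <- knots[k, 2]
    t1 <- knots[k + 1, 1]; v1 <- knots[k + 1, 2]
    sel <- times > t0 & times <= t1
    if (!any(sel)) next
    if (v0 == v1) {
      env[sel] <- v0
    } else {
      ph <- (times[sel] - t0) / (t1 - t0)
      env[sel] <- v0 + (v1 - v0) * (1 - cos(pi * ph)) / 2
    }
  }
  env[times > knots[6, 1]] <- 1
  env
}
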