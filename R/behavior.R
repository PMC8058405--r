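#' Smooth a running-speed trace with a moving median
#'
#' Applies a centered moving-median filter of width `window_s` (200 ms by
#' default, the width used for artifact suppression on optical-mouse speed
#' traces). The window length in samples is forced odd; the ends are smoothed
#' with successively shrinking windows so the output has the same length as
#' the input.
#'
#' @param trace A [behavior_trace()] with uniform sampling.
#' @param window_s Window width in seconds.
#' @return A smoothed `behavior_trace` of identical length and time base.
#' @export
smooth_running <- function(trace, window_s = 0.2) {
  if (length(trace$v) == 0) stop("cannot smooth an empty trace")
  k <- round(window_s * trace$rate_hz)
  if (k %% 2 == 0) k <- k + 1L
  k <- max(1L, min(k, length(trace$v) - (1 - length(trace$v) %% 2)))
  if (k <= 1 || length(trace$v) < 3) return(trace)
  sm <- as.numeric(stats::runmed(trace$v, k, endrule = "median"))
  behavior_trace(trace$t, sm, trace$rate_hz)
}

#' Label trials as running or sitting and apply the session-inclusion rule
#'
#' Each trial's mean (smoothed) speed over the stimulus window
#' `[onset, onset + duration)` is compared with a fraction of the session's
#' maximum smoothed speed: trials strictly above `threshold_fraction *
#' max_speed` are labelled running, others sitting. Sessions with fewer than
#' `min_running_trials` running trials are flagged as excluded from
#' running/sitting analyses.
#'
#' @param trials A [trial_table()].
#' @param speed A smoothed running-speed [behavior_trace()] covering all
#'   trial windows (see [smooth_running()]).
#' @param threshold_fraction Fraction of maximum speed above which a trial is
#'   running (default 0.05, i.e. 5 percent).
#' @param min_running_trials Minimum number of running trials for the session
#'   to enter running/sitting analyses (default 7).
#' @return A list of class `state_labeling` with elements `trials` (the table
#'   with `mean_speed` and `state` filled), `max_speed`, `n_running`,
#'   `n_sitting` and `included`.
#' @export
label_trials <- function(trials, speed, threshold_fraction = 0.05,
                         min_running_trials = 7) {
  if (!length(speed$v)) stop("speed trace is empty")
  t0 <- min(speed$t); t1 <- max(speed$t)
  ms <- vapply(seq_len(nrow(trials)), function(i) {
    a <- trials$onset_s[i]; b <- a + trials$duration_s[i]
    if (a < t0 - 1e-9 || b > t1 + 1 / speed$rate_hz + 1e-9) {
      stop("trial ", i, " window [", a, ", ", b, ") outside speed trace support")
    }
    sel <- speed$t >= a & speed$t < b
    if (!any(sel)) stop("trial ", i, ": no speed samples in stimulus window")
    mean(speed$v[sel])
  }, 0)
  max_speed <- max(speed$v)
  state <- ifelse(ms > threshold_fraction * max_speed, "running", "sitting")
  out <- trials
  out$mean_speed <- ms
  out$state <- state
  n_running <- sum(state == "running")
  structure(list(trials = out, max_speed = max_speed, n_running = n_running,
                 n_sitting = sum(state == "sitting"),
                 included = n_running >= min_running_trials,
                 threshold_fraction = threshold_fraction,
                 min_running_trials = min_running_trials),
            class = "state_labeling")
}

#' High-arousal mask from a pupil trace
#'
#' Marks samples where pupil size is strictly above a fraction of the session
#' maximum (default 60 percent), the arousal regime within which running
#' bouts occur.
#'
#' A perfectly flat trace carries no arousal modulation, so no sample is
#' flagged as high-arousal in that degenerate case.
#'
#' @param pupil A pupil [behavior_trace()] (fraction of maximum), or `NULL`.
#' @param fraction Fraction of the maximum recorded pupil size.
#' @return A list with `available` (logical) and, when available, logical
#'   `mask` per sample; `available = FALSE` with a `reason` when no pupil
#'   trace was recorded.
#' @export
arousal_gate <- function(pupil, fraction = 0.60) {
  if (is.null(pupil) || !length(pupil$v)) {
    return(list(available = FALSE, mask = NULL, reason = "no pupil trace"))
  }
  flat <- max(pupil$v) == min(pupil$v)
  mask <- if (flat) rep(FALSE, length(pupil$v)) else
    pupil$v > fraction * max(pupil$v)
  list(available = TRUE, mask = mask, fraction = fraction)
}
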