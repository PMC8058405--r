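# Per-unit, per-condition firing-rate metrics. Analysis windows relative to
# stimulus onset: onset response 0-100 ms, offset response 600-700 ms (i.e.
# the 100 ms after the 600 ms stimulus ends), spontaneous rate from the
# interleaved blank trials over the matching windows. Trial windows are
# half-open [t0, t1) so boundary spikes count exactly once.

count_in_windows <- function(spike_times, starts, ends) {
  # spikes in [start, end): #{t < end} - #{t < start}
  findInterval(ends, spike_times, left.open = TRUE) -
    findInterval(starts, spike_times, left.open = TRUE)
}

#' Select trials by stimulus kind, laser state and behavioral state
#'
#' @param trials A [trial_table()].
#' @param stim `"WN"`, `"blank"` or `"either"`.
#' @param laser `"on"`, `"off"` or `"either"`.
#' @param state `"running"`, `"sitting"` or `"either"`.
#' @return The matching subset of the trial table.
#' @export
select_trials <- function(trials, stim = "either", laser = "either",
                          state = "either") {
  sel <- rep(TRUE, nrow(trials))
  if (stim != "either") sel <- sel & trials$stim == stim
  if (laser != "either") sel <- sel & trials$laser == laser
  if (state != "either") sel <- sel & trials$state == state
  trials[sel, , drop = FALSE]
}

#' Per-trial firing rates in a window relative to stimulus onset
#'
#' @param u A [unit()].
#' @param trials Trial table rows to evaluate (pre-filter with
#'   [select_trials()]).
#' @param window Length-2 numeric `(t0, t1)` seconds relative to onset; the
#'   rate is the spike count in `[onset + t0, onset + t1)` divided by
#'   `t1 - t0`.
#' @return Numeric vector of rates in Hz, one per trial.
#' @export
trial_rates <- function(u, trials, window = c(0, 0.1)) {
  if (nrow(trials) == 0) stop("empty trial selection for unit ", u$unit_id)
  starts <- trials$onset_s + window[1]
  ends <- trials$onset_s + window[2]
  count_in_windows(u$spike_times, starts, ends) / (window[2] - window[1])
}

#' Test for a significant sound-evoked increase in firing
#'
#' Two-sided Wilcoxon rank-sum test between per-trial onset-window rates on
#' white-noise trials and the matched window on interleaved blank trials
#' (laser-off, sitting). A unit is scored as significantly sound-responsive
#' only for an *increase*: `p < alpha` and mean WN rate above mean blank
#' rate. Exact p-values are used when both samples have at most 25 trials
#' and no ties; otherwise the normal approximation.
#'
#' @param u A [unit()].
#' @param trials A labelled [trial_table()].
#' @param alpha Significance level (default 0.01).
#' @param window Analysis window relative to onset (default onset window).
#' @param state Behavioral state to condition on (default `"sitting"`;
#'   `"either"` when trial states are not labelled).
#' @return List with `sig_increase`, `p`, `mean_wn`, `mean_blank`.
#' @export
significant_evoked <- function(u, trials, alpha = 0.01, window = c(0, 0.1),
                               state = "sitting") {
  wn <- select_trials(trials, stim = "WN", laser = "off", state = state)
  bl <- select_trials(trials, stim = "blank", laser = "off", state = state)
  if (nrow(wn) < 2 || nrow(bl) < 2) {
    stop("insufficient laser-off trials for significance test (unit ",
         u$unit_id, ")")
  }
  rw <- trial_rates(u, wn, window)
  rb <- trial_rates(u, bl, window)
  exact <- nrow(wn) <= 25 && nrow(bl) <= 25
  p <- suppressWarnings(stats::wilcox.test(rw, rb, exact = exact)$p.value)
  if (is.nan(p)) p <- 1
  list(sig_increase = is.finite(p) && p < alpha && mean(rw) > mean(rb),
       p = p, mean_wn = mean(rw), mean_blank = mean(rb))
}

#' Peri-stimulus time histogram
#'
#' Trial-averaged firing rate in fixed bins (5 ms by default) relative to
#' stimulus onset.
#'
#' @param u A [unit()].
#' @param trials Trial rows to average over.
#' @param range Length-2 window relative to onset, seconds.
#' @param bin_s Bin width, seconds.
#' @return List with `t` (bin centers, s) and `rate_hz`.
#' @export
psth <- function(u, trials, range = c(-0.05, 0.8), bin_s = 0.005) {
  if (nrow(trials) == 0) stop("empty trial selection for PSTH")
  edges <- seq(range[1], range[2], by = bin_s)
  n_bins <- length(edges) - 1L
  counts <- numeric(n_bins)
  for (o in trials$onset_s) {
    counts <- counts + count_in_windows(u$spike_times, o + edges[-length(edges)],
                                        o + edges[-1])
  }
  list(t = edges[-length(edges)] + bin_s / 2,
       rate_hz = counts / (nrow(trials) * bin_s))
}

#' Sound-response latency from the smoothed PSTH
#'
#' Computes a 5 ms-bin PSTH, smooths it with a 15 ms (3-bin) centered moving
#' average, and returns the first post-onset time at which the smoothed rate
#' crosses half of its post-onset peak (halfway between 0 Hz and the peak),
#' with linear interpolation between bin centers.
#'
#' @param u A [unit()].
#' @param trials WN trial rows of the condition of interest.
#' @param search Post-onset window within which the peak and crossing are
#'   sought, seconds.
#' @param bin_s PSTH bin width (default 5 ms).
#' @param smooth_s Moving-average width (default 15 ms).
#' @return Latency in seconds, or `NA` when the smoothed peak is 0 Hz.
#' @export
response_latency <- function(u, trials, search = c(0, 0.2), bin_s = 0.005,
                             smooth_s = 0.015) {
  p <- psth(u, trials, range = c(search[1] - smooth_s, search[2] + smooth_s),
            bin_s = bin_s)
  k <- max(1L, round(smooth_s / bin_s))
  if (k %% 2 == 0) k <- k + 1L
  sm <- stats::filter(p$rate_hz, rep(1 / k, k), sides = 2)
  sm <- as.numeric(sm)
  keep <- which(p$t >= search[1] & p$t <= search[2] & !is.na(sm))
  tt <- p$t[keep]; y <- sm[keep]
  pk <- max(y)
  if (pk <= 0) return(NA_real_)
  half <- pk / 2
  i <- which(y >= half)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1 || y[i] == y[i - 1]) return(tt[i])
  # linear interpolation between the bin below and the crossing bin
  tt[i - 1] + (half - y[i - 1]) / (y[i] - y[i - 1]) * (tt[i] - tt[i - 1])
}

#' Summarize responses of all units across the four state x laser conditions
#'
#' For every unit and every combination of state (sitting/running) and laser
#' (off/on): the spontaneous rate (blank trials, full stimulus-equivalent
#' window), onset rate (WN trials, 0-100 ms), offset rate (WN trials, the
#' 100 ms after stimulus offset) and trial counts. The sound-responsiveness
#' flag (`sig_increase`) is computed once per unit from sitting laser-off
#' trials.
#'
#' @param s An `ephys_session` whose trials are state-labelled.
#' @param alpha Significance level for the evoked-increase test.
#' @param min_trials Minimum trials for a condition entry to be computed.
#' @return A `data.frame`, one row per unit x condition, with columns
#'   `unit_id`, `state`, `laser`, `spont_hz`, `onset_hz`, `offset_hz`,
#'   `n_wn`, `n_blank`, `sig_increase`, `p_sig`.
#' @export
response_summary <- function(s, alpha = 0.01, min_trials = 7) {
  stopifnot(!any(s$trials$state == "unfilled"))
  dur <- s$meta$stim_dur_s
  onset_w <- c(0, 0.1)
  offset_w <- c(dur, dur + 0.1)
  conds <- expand.grid(state = c("sitting", "running"), laser = c("off", "on"),
                       stringsAsFactors = FALSE)
  rows <- list()
  for (u in s$units) {
    sig <- tryCatch(significant_evoked(u, s$trials, alpha = alpha),
                    error = function(e) list(sig_increase = NA, p = NA_real_))
    for (i in seq_len(nrow(conds))) {
      wn <- select_trials(s$trials, "WN", conds$laser[i], conds$state[i])
      bl <- select_trials(s$trials, "blank", conds$laser[i], conds$state[i])
      enough <- nrow(wn) >= min_trials && nrow(bl) >= min_trials
      rows[[length(rows) + 1L]] <- data.frame(
        unit_id = u$unit_id, state = conds$state[i], laser = conds$laser[i],
        spont_hz = if (enough) mean(trial_rates(u, bl, c(0, dur))) else NA_real_,
        onset_hz = if (enough) mean(trial_rates(u, wn, onset_w)) else NA_real_,
        offset_hz = if (enough) mean(trial_rates(u, wn, offset_w)) else NA_real_,
        n_wn = nrow(wn), n_blank = nrow(bl),
        sig_increase = sig$sig_increase, p_sig = sig$p,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
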