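#' Acquisition metadata for a stimulation session
#'
#' Describes the stimulus/laser schedule used during recording: 600 ms white
#' noise (WN) bursts at 1 s inter-stimulus interval, randomly interleaved with
#' silent blanks, each presented with and without an 800 ms laser pulse that
#' starts 50 ms before sound onset and ends 150 ms after sound offset.
#'
#' @param stim_dur_s Stimulus duration in seconds.
#' @param isi_s Inter-stimulus interval (silent gap between stimuli), seconds.
#' @param laser_pre_s Laser lead time before sound onset, seconds.
#' @param laser_post_s Laser lag after sound offset, seconds.
#' @param min_reps_per_combo Minimum repeats required per stimulus x laser
#'   combination.
#' @return An object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(stim_dur_s = 0.6, isi_s = 1.0,
                             laser_pre_s = 0.05, laser_post_s = 0.15,
                             min_reps_per_combo = 30) {
  meta <- list(
    stim_dur_s = stim_dur_s,
    isi_s = isi_s,
    laser_pre_s = laser_pre_s,
    laser_post_s = laser_post_s,
    laser_dur_s = stim_dur_s + laser_pre_s + laser_post_s,
    min_reps_per_combo = as.integer(min_reps_per_combo)
  )
  class(meta) <- "acquisition_meta"
  meta
}

#' Construct a sorted unit
#'
#' One spike-sorted neuron: its spike times, mean waveforms (one row per probe
#' channel), and placeholders for the depth, layer and cell class filled in by
#' the laminar and waveform-classification stages.
#'
#' @param unit_id Unique unit identifier (character).
#' @param spike_times Numeric vector of spike times in seconds, sorted
#'   ascending, all nonnegative.
#' @param waveforms Channels x samples matrix of mean waveforms (microvolts),
#'   or `NULL` when unavailable.
#' @param waveform_rate_hz Sampling rate of the waveform, Hz.
#' @param peak_channel 1-based index of the channel with the largest
#'   peak-to-trough waveform amplitude; computed from `waveforms` when `NULL`.
#' @param depth_um Cortical depth in micrometers (`NA` until assigned).
#' @param layer Cortical layer label, one of `"L1"`, `"L2/3"`, `"L4"`, `"L5"`,
#'   `"L6"`, `"unassigned"`.
#' @param cell_class `"NS"`, `"RS"` or `"unclassified"`.
#' @return An object of class `ephys_unit`.
#' @export
unit <- function(unit_id, spike_times, waveforms = NULL,
                 waveform_rate_hz = 30000, peak_channel = NULL,
                 depth_um = NA_real_, layer = "unassigned",
                 cell_class = "unclassified") {
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times)) {
    stop("spike_times must be sorted ascending for unit '", unit_id, "'")
  }
  if (!is.null(waveforms)) {
    waveforms <- as.matrix(waveforms)
    if (is.null(peak_channel)) {
      amp <- apply(waveforms, 1L, function(w) max(w) - min(w))
      peak_channel <- which.max(amp)
    }
  }
  u <- list(
    unit_id = as.character(unit_id),
    spike_times = spike_times,
    waveforms = waveforms,
    waveform_rate_hz = waveform_rate_hz,
    peak_channel = if (is.null(peak_channel)) NA_integer_ else as.integer(peak_channel),
    depth_um = depth_um,
    layer = layer,
    cell_class = cell_class
  )
  class(u) <- "ephys_unit"
  u
}

#' Construct a trial table
#'
#' @param onset_s Stimulus onset times in seconds.
#' @param stim Stimulus kind per trial: `"WN"` (white noise) or `"blank"`.
#' @param laser Laser state per trial: `"on"` or `"off"`.
#' @param duration_s Stimulus duration per trial, seconds (recycled).
#' @return A `data.frame` of class `trial_table` with columns `onset_s`,
#'   `stim`, `laser`, `duration_s`, `mean_speed` and `state` (the last two
#'   unfilled until [label_trials()] runs).
#' @export
trial_table <- function(onset_s, stim, laser, duration_s = 0.6) {
  n <- length(onset_s)
  tt <- data.frame(
    onset_s = as.numeric(onset_s),
    stim = as.character(stim),
    laser = as.character(laser),
    duration_s = rep_len(as.numeric(duration_s), n),
    mean_speed = rep(NA_real_, n),
    state = rep("unfilled", n),
    stringsAsFactors = FALSE
  )
  stopifnot(all(tt$stim %in% c("WN", "blank")), all(tt$laser %in% c("on", "off")))
  class(tt) <- c("trial_table", "data.frame")
  tt
}

#' Construct a uniformly sampled behavioral trace
#'
#' @param t Sample times, seconds, uniformly spaced.
#' @param v Values (running speed in cm/s, or pupil size as fraction of max).
#' @param rate_hz Sampling rate; inferred from `t` when `NULL`.
#' @return An object of class `behavior_trace`.
#' @export
behavior_trace <- function(t, v, rate_hz = NULL) {
  if (length(t) != length(v)) stop("t and v must have equal length")
  if (is.null(rate_hz)) {
    rate_hz <- if (length(t) > 1) 1 / stats::median(diff(t)) else NA_real_
  }
  tr <- list(t = as.numeric(t), v = as.numeric(v), rate_hz = rate_hz)
  class(tr) <- "behavior_trace"
  tr
}

#' Construct a multichannel LFP block
#'
#' @param data Channels x samples matrix, microvolts, channels ordered
#'   superficial to deep (row 1 = most superficial site).
#' @param spacing_um Inter-site spacing along the probe, micrometers.
#' @param rate_hz Sampling rate, Hz.
#' @param filtered_band Length-2 numeric `(low, high)` Hz if the data were
#'   already band-limited, else `NULL`.
#' @return An object of class `lfp_block`.
#' @export
lfp_block <- function(data, spacing_um = 25, rate_hz, filtered_band = NULL) {
  data <- as.matrix(data)
  blk <- list(data = data, spacing_um = spacing_um, rate_hz = rate_hz,
              filtered_band = filtered_band)
  class(blk) <- "lfp_block"
  blk
}

#' Construct a recording session
#'
#' Container binding sorted units, the trial table, behavioral traces, the
#' optional LFP block and acquisition metadata.
#'
#' @param session_id Character identifier.
#' @param units List of [unit()] objects.
#' @param trials A [trial_table()].
#' @param running [behavior_trace()] of running speed (cm/s).
#' @param pupil Optional [behavior_trace()] of pupil size (fraction of max).
#' @param lfp Optional [lfp_block()].
#' @param meta [acquisition_meta()].
#' @param duration_s Recording duration; inferred from content when `NULL`.
#' @return An object of class `ephys_session`.
#' @export
session <- function(session_id, units, trials, running, pupil = NULL,
                    lfp = NULL, meta = acquisition_meta(), duration_s = NULL) {
  if (is.null(duration_s)) {
    cand <- c(
      if (nrow(trials) > 0) max(trials$onset_s + trials$duration_s) else 0,
      if (length(running$t) > 0) max(running$t) else 0,
      vapply(units, function(u) if (length(u$spike_times)) max(u$spike_times) else 0, 0)
    )
    duration_s <- max(cand)
  }
  s <- list(session_id = as.character(session_id), units = units,
            trials = trials, running = running, pupil = pupil, lfp = lfp,
            meta = meta, duration_s = duration_s)
  class(s) <- "ephys_session"
  s
}

#' @export
print.ephys_session <- function(x, ...) {
  cat("<ephys_session>", x$session_id, "\n")
  cat("  units:", length(x$units), " trials:", nrow(x$trials),
      " duration:", round(x$duration_s, 2), "s\n")
  cat("  lfp:", if (is.null(x$lfp)) "absent" else
    paste0(nrow(x$lfp$data), " ch @ ", x$lfp$rate_hz, " Hz"),
    " pupil:", if (is.null(x$pupil)) "absent" else "present", "\n")
  invisible(x)
}

#' Validate a session against its structural invariants
#'
#' Checks the invariants every downstream operation relies on: spike times in
#' `[0, duration]` and sorted, unique unit ids, trial onsets within the
#' recording, trial spacing at least one stimulus duration, laser window
#' consistency, and (when present) an LFP block with at least three channels
#' so that a current source density can be formed.
#'
#' @param s An `ephys_session`.
#' @return Character vector of violation descriptions; empty when valid.
#' @export
validate_session <- function(s) {
  v <- character()
  ids <- vapply(s$units, function(u) u$unit_id, "")
  if (anyDuplicated(ids)) v <- c(v, "unit ids are not unique")
  for (u in s$units) {
    st <- u$spike_times
    if (length(st)) {
      if (is.unsorted(st)) {
        v <- c(v, sprintf("unit %s: spike times not sorted", u$unit_id))
      }
      if (min(st) < 0 || max(st) > s$duration_s + 1e-9) {
        v <- c(v, sprintf("unit %s: spike times outside [0, duration]", u$unit_id))
      }
    }
    if (!is.na(u$depth_um) && (u$depth_um < 0 || u$depth_um > 1200)) {
      v <- c(v, sprintf("unit %s: assigned depth outside [0, 1200] um", u$unit_id))
    }
  }
  tt <- s$trials
  if (nrow(tt)) {
    if (min(tt$onset_s) < 0 || max(tt$onset_s + tt$duration_s) > s$duration_s + 1e-9) {
      v <- c(v, "trial onsets outside [0, recording duration]")
    }
    if (nrow(tt) > 1) {
      gaps <- diff(sort(tt$onset_s))
      if (any(gaps < tt$duration_s[1] - 1e-9)) {
        v <- c(v, "inter-trial onset spacing below stimulus duration")
      }
    }
    done <- !any(tt$state == "unfilled")
    if (!done && !all(tt$state == "unfilled")) {
      v <- c(v, "trial states partially filled")
    }
  }
  if (!is.null(s$lfp)) {
    if (nrow(s$lfp$data) < 3) v <- c(v, "CSD requires >=3 channels")
    if (s$lfp$spacing_um <= 0) v <- c(v, "LFP spacing must be positive")
  }
  if (length(s$running$t) != length(s$running$v)) {
    v <- c(v, "running trace t/v length mismatch")
  } else if (length(s$running$t) > 2) {
    d <- diff(s$running$t)
    if (max(d) - min(d) > 1.5 / s$running$rate_hz) {
      v <- c(v, "running trace not uniformly sampled")
    }
  }
  m <- s$meta
  if (abs(m$laser_dur_s - (m$stim_dur_s + m$laser_pre_s + m$laser_post_s)) > 1e-9) {
    v <- c(v, "laser duration != stim duration + pre + post")
  }
  v
}
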