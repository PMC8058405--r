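#' Measure spike-waveform features
#'
#' Measures, on the peak-channel mean waveform: the peak-to-trough width
#' (time from the global trough to the subsequent positive peak, the
#' extracellular convention), the end-slope (least-squares slope over the
#' final `end_window_ms` of the waveform, in uV/ms), and the peak-to-trough
#' amplitude ratio.
#'
#' @param wf Numeric vector, the unit's mean waveform on its peak channel (uV).
#' @param rate_hz Waveform sampling rate, Hz.
#' @param end_window_ms Terminal epoch over which the end-slope is fit.
#' @return A list of class `waveform_features` with `width_ms`, `end_slope`
#'   (uV/ms) and `peak_trough_ratio`.
#' @export
waveform_features <- function(wf, rate_hz, end_window_ms = 0.2) {
  wf <- as.numeric(wf)
  n <- length(wf)
  trough <- which.min(wf)
  if (trough >= n) stop("no trough/peak pair: trough at waveform end")
  after <- wf[(trough + 1L):n]
  peak <- trough + which.max(after)
  if (wf[peak] <= wf[trough]) stop("no trough/peak pair: waveform monotone")
  width_ms <- (peak - trough) / rate_hz * 1000
  m <- max(2L, round(end_window_ms / 1000 * rate_hz))
  tail_idx <- (n - m + 1L):n
  tt <- (tail_idx - 1) / rate_hz * 1000  # ms
  yy <- wf[tail_idx]
  end_slope <- stats::cov(tt, yy) / stats::var(tt)
  structure(list(width_ms = width_ms, end_slope = end_slope,
                 peak_trough_ratio = abs(wf[peak]) / abs(wf[trough])),
            class = "waveform_features")
}

#' Classify a unit as narrow- or regular-spiking
#'
#' Narrow-spiking (NS, putative fast-spiking interneuron): width strictly
#' below the threshold (0.5 ms) and negative end-slope. Regular-spiking (RS,
#' putative excitatory): width at or above the threshold. Units below the
#' width threshold with a nonnegative end-slope fall in neither rule and are
#' returned `"unclassified"`.
#'
#' @param f A `waveform_features` object (or list with `width_ms`,
#'   `end_slope`).
#' @param width_threshold_ms Width threshold, ms.
#' @return `"NS"`, `"RS"` or `"unclassified"`.
#' @export
classify_unit <- function(f, width_threshold_ms = 0.5) {
  if (f$width_ms >= width_threshold_ms) return("RS")
  if (f$end_slope < 0) return("NS")
  "unclassified"
}

#' Classify every unit in a session from its waveforms
#'
#' @param s An `ephys_session` whose units carry waveforms.
#' @param width_threshold_ms Width threshold, ms.
#' @return The session with each unit's `cell_class` filled in; units
#'   without waveforms stay `"unclassified"`.
#' @export
classify_cells <- function(s, width_threshold_ms = 0.5) {
  s$units <- lapply(s$units, function(u) {
    if (is.null(u$waveforms)) return(u)
    wf <- u$waveforms[u$peak_channel, ]
    u$cell_class <- classify_unit(waveform_features(wf, u$waveform_rate_hz),
                                  width_threshold_ms)
    u
  })
  s
}
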