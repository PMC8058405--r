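# Fixtures are built in code; nothing is stored on disk.

# A tiny hand-built session: 8 trials (2 per stim x laser combination),
# 2 units with known spike times, a flat running trace, no LFP.
tiny_session <- function(with_lfp = FALSE) {
  tt <- trial_table(
    onset_s = 1 + (0:7) * 1.6,
    stim = rep(c("WN", "blank"), 4),
    laser = rep(c("off", "off", "on", "on"), 2)
  )
  dur <- max(tt$onset_s) + 1.6
  tr <- behavior_trace(seq(0, dur, by = 0.01), rep(0.01, length(seq(0, dur, by = 0.01))),
                       rate_hz = 100)
  wf <- generate_waveform("RS", seed = 5, width_ms = 0.7)
  u1 <- unit("u1", c(1.05, 1.25, 2.61, 4.2), waveforms = wf)
  u2 <- unit("u2", c(0.5, 3.3, 7.7), waveforms = wf)
  lfp <- NULL
  if (with_lfp) {
    lfp <- lfp_block(matrix(rnorm(5 * 100), 5, 100), spacing_um = 25, rate_hz = 100)
  }
  session("tiny", list(u1, u2), tt, tr, lfp = lfp, duration_s = dur)
}

# Deterministic spike train: `offsets` seconds after each trial onset.
spikes_at <- function(onsets, offsets) {
  sort(as.numeric(outer(onsets, offsets, `+`)))
}

# One offset per onset (recycled), for unequal per-trial patterns.
spikes_at_each <- function(onsets, offsets) {
  sort(onsets + rep_len(offsets, length(onsets)))
}

# Independent naive distance-correlation oracle (explicit double loops over
# the double-centering definition; no shared code with the implementation).
naive_dcor <- function(X, y) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  n <- ncol(X)
  dmat <- function(M) {
    D <- matrix(0, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        D[i, j] <- sqrt(sum((M[, i] - M[, j])^2))
      }
    }
    D
  }
  cent <- function(D) {
    A <- matrix(0, n, n)
    gm <- mean(D)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        A[i, j] <- D[i, j] - mean(D[i, ]) - mean(D[, j]) + gm
      }
    }
    A
  }
  A <- cent(dmat(X)); B <- cent(dmat(y))
  dcov2 <- mean(A * B)
  dvx <- mean(A * A); dvy <- mean(B * B)
  if (dvx <= 0 || dvy <= 0) return(0)
  sqrt(max(dcov2, 0)) / (dvx * dvy)^0.25
}

# Label trial states straight from a session's running trace.
label_session <- function(s, ...) {
  s$trials <- label_trials(s$trials, smooth_running(s$running), ...)$trials
  s
}
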