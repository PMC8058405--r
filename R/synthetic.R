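# Synthetic-session generator with recoverable ground truth.
#
# Emulates the recording protocol: 600 ms white-noise bursts at 1 s ISI
# randomly interleaved with silent blanks, each with and without an 800 ms
# laser pulse (on from 50 ms before sound onset to 150 ms after offset), at
# least 30 repeats per combination; bout-structured running on ~13% of
# trials; Poisson spiking with additive condition-dependent rate increments;
# a stimulus-evoked LFP sink/source dipole at the L3/L4 boundary (400 um);
# and NS/RS waveform templates separated at 0.5 ms peak-to-trough width.
#
# Rate model per unit (Hz), all increments additive and clipped at 0:
#   spontaneous = base + run_spont_delta*running + laser_spont_delta*laser
#   onset window [latency, latency + 100 ms]: + onset_gain
#       + run_evoked_delta*running + laser_evoked_delta*laser
#   offset window [600 + latency, 700 + latency] ms: + offset_gain + deltas
# On running laser-on trials the summed running + laser increments are
# multiplied by `interaction_scale` (1 = exact additivity; < 1 injects a
# sub-additive multiplicative interaction).
#
# Default per-unit parameter distributions are calibrated to the published
# population means of awake mouse auditory cortex under this protocol
# (spontaneous sitting 4.87 Hz / running 6.50 Hz; onset evoked sitting
# 15.81 Hz / running 13.97 Hz; NS/RS spontaneous running deltas +2.70/+1.27
# Hz; running on ~13% of trials at ~7 cm/s). Evoked gains are divided by the
# fraction of the 100 ms analysis window that follows the mean latency so
# that *measured* window rates, not instantaneous rates, hit those targets.

#' Parameters for the synthetic-session generator
#'
#' @param n_units Number of units.
#' @param seed Master seed; every draw derives from it via labelled
#'   sub-streams, so the same params generate identical sessions.
#' @param p_ns Probability a unit is narrow-spiking.
#' @param layer_weights Named weights over true layers.
#' @param n_trials_per_combo Trials per stimulus x laser combination (>= 30).
#' @param spont_mean_hz,spont_shape Gamma distribution of baseline
#'   spontaneous rate.
#' @param onset_gain_mean_hz,offset_gain_mean_hz,evoked_shape Gamma means and
#'   shape of the evoked onset/offset increments (instantaneous; see above).
#' @param run_spont_delta_rs_hz,run_spont_delta_ns_hz,run_spont_sd_hz Normal
#'   spontaneous running increments by cell class.
#' @param run_evoked_delta_hz,run_evoked_sd_hz Normal evoked running
#'   increment (instantaneous).
#' @param laser_spont_delta_hz,laser_spont_sd_hz,laser_evoked_delta_hz,laser_evoked_sd_hz
#'   Laser (VIP activation) increments.
#' @param latency_mean_s,latency_sd_s Response latency distribution.
#' @param interaction_scale Scale on summed increments when running and laser
#'   coincide (1 = additive).
#' @param trace_rate_hz Running/pupil trace sampling rate.
#' @param mean_run_bout_s,mean_sit_bout_s Mean dwell times of the two-state
#'   bout process (defaults give ~13% running).
#' @param speed_mu_cmps,speed_sd_cmps,sit_speed_cmps,ramp_s Bout speed
#'   distribution, stationary baseline speed, and raised-cosine ramp width.
#' @param with_lfp,with_pupil Generate the optional LFP block / pupil trace.
#' @param n_channels,spacing_um,probe_offset_um Probe geometry (channel 1
#'   most superficial at `probe_offset_um` below the pia).
#' @param lfp_rate_hz,lfp_noise_uv,dipole_amp_uv,dipole_sigma_um,dipole_tau_s,sink_depth_um
#'   LFP sampling rate, spatially smooth noise scale, and evoked dipole
#'   amplitude, spatial width, time constant and center depth.
#' @param wf_rate_hz,wf_amp_uv,wf_lambda_um Waveform sampling rate, peak
#'   amplitude and across-channel decay length.
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(
    n_units = 235, seed = 1, p_ns = 0.25,
    layer_weights = c("L2/3" = 0.20, "L4" = 0.20, "L5" = 0.45, "L6" = 0.15),
    n_trials_per_combo = 30,
    spont_mean_hz = 4.87, spont_shape = 1,
    onset_gain_mean_hz = 10.94 / 0.85, offset_gain_mean_hz = 7.98 / 0.85,
    evoked_shape = 1,
    run_spont_delta_rs_hz = 1.27, run_spont_delta_ns_hz = 2.70,
    run_spont_sd_hz = 2.0,
    run_evoked_delta_hz = -3.47 / 0.85, run_evoked_sd_hz = 4.0,
    laser_spont_delta_hz = 1.5, laser_spont_sd_hz = 2.0,
    laser_evoked_delta_hz = 1.5 / 0.85, laser_evoked_sd_hz = 3.0,
    latency_mean_s = 0.015, latency_sd_s = 0.003,
    interaction_scale = 1,
    trace_rate_hz = 100,
    mean_run_bout_s = 5, mean_sit_bout_s = 33,
    speed_mu_cmps = 7, speed_sd_cmps = 1, sit_speed_cmps = 0.02, ramp_s = 0.2,
    with_lfp = TRUE, with_pupil = TRUE,
    n_channels = 32, spacing_um = 25, probe_offset_um = 150,
    lfp_rate_hz = 1000, lfp_noise_uv = 75, dipole_amp_uv = 100,
    dipole_sigma_um = 35, dipole_tau_s = 0.012, sink_depth_um = 400,
    wf_rate_hz = 30000, wf_amp_uv = 150, wf_lambda_um = 60) {
  p <- as.list(environment())
  stopifnot(p$n_trials_per_combo >= 1, p$n_units >= 1, p$n_channels >= 3)
  class(p) <- "generator_params"
  p
}

#' Generate a spike-waveform template of a given cell class
#'
#' Biphasic template (negative trough followed by a positive peak) whose
#' trough-to-peak width is drawn below 0.5 ms for NS and at or above 0.55 ms
#' for RS, with a decaying positive tail (negative end-slope). Across
#' channels the amplitude peaks at the channel nearest the unit's depth and
#' decays exponentially with distance.
#'
#' @param class `"NS"` or `"RS"`.
#' @param seed RNG seed (`NULL` uses the current stream).
#' @param width_ms Fixed trough-to-peak width; drawn from the class range
#'   when `NULL` (NS: 0.25-0.45 ms, RS: 0.55-1.0 ms).
#' @param rate_hz Waveform sampling rate.
#' @param channel_depths Depths (um) of the probe channels; `NULL` gives a
#'   single-channel template.
#' @param depth_um True depth of the unit (required with `channel_depths`).
#' @param amp_uv Trough amplitude at the peak channel.
#' @param lambda_um Amplitude decay length across channels.
#' @return Channels x samples waveform matrix (single row when
#'   `channel_depths` is `NULL`).
#' @export
generate_waveform <- function(class = c("NS", "RS"), seed = NULL,
                              width_ms = NULL, rate_hz = 30000,
                              channel_depths = NULL, depth_um = NULL,
                              amp_uv = 150, lambda_um = 60) {
  class <- match.arg(class)
  draw <- function() {
    if (is.null(width_ms)) {
      if (class == "NS") stats::runif(1, 0.25, 0.45) else stats::runif(1, 0.55, 1.0)
    } else width_ms
  }
  w <- if (is.null(seed)) draw() else local_seed(seed, draw())
  n <- round(0.0027 * rate_hz)
  t_ms <- (seq_len(n) - 1) / rate_hz * 1000
  t_tr <- 0.9
  sig1 <- 0.1
  sig2 <- max(0.12, 0.3 * w)
  shape <- -exp(-(t_ms - t_tr)^2 / (2 * sig1^2)) +
    0.45 * exp(-(t_ms - (t_tr + w))^2 / (2 * sig2^2))
  shape <- shape / max(abs(shape))
  if (is.null(channel_depths)) {
    return(matrix(amp_uv * shape, nrow = 1))
  }
  stopifnot(!is.null(depth_um))
  fac <- exp(-abs(channel_depths - depth_um) / lambda_um)
  outer(fac, amp_uv * shape)
}

# Two-state (sit/run) bout process sampled at trace rate, with per-bout
# target speeds and raised-cosine ramps. Returns speed and binary indicator.
make_running_trace <- function(duration_s, p) {
  n <- ceiling(duration_s * p$trace_rate_hz) + 1L
  dt <- 1 / p$trace_rate_hz
  ind <- numeric(n)
  target <- numeric(n)
  t_cur <- 0
  running <- FALSE
  while (t_cur < duration_s) {
    dwell <- if (running) {
      max(0.8, stats::rexp(1, 1 / p$mean_run_bout_s))
    } else {
      max(1.0, stats::rexp(1, 1 / p$mean_sit_bout_s))
    }
    i0 <- floor(t_cur / dt) + 1L
    i1 <- min(n, floor((t_cur + dwell) / dt))
    if (running && i1 >= i0) {
      ind[i0:i1] <- 1
      target[i0:i1] <- max(2, stats::rnorm(1, p$speed_mu_cmps, p$speed_sd_cmps))
    }
    t_cur <- t_cur + dwell
    running <- !running
  }
  # raised-cosine ramp of width ramp_s
  k <- max(1L, round(p$ramp_s * p$trace_rate_hz))
  kern <- 0.5 * (1 - cos(2 * pi * seq_len(k) / (k + 1)))
  kern <- kern / sum(kern)
  sm <- stats::filter(target, kern, sides = 2)
  sm[is.na(sm)] <- 0
  base <- p$sit_speed_cmps + abs(stats::rnorm(n, 0, p$sit_speed_cmps / 4))
  speed <- pmax(as.numeric(sm), base)
  list(t = (seq_len(n) - 1) * dt, speed = speed, indicator = ind)
}

make_pupil_trace <- function(indicator, rate_hz) {
  n <- length(indicator)
  widen <- round(rate_hz * 1.0)
  box <- rep(1, 2 * widen + 1)
  wide <- as.numeric(stats::filter(indicator, box, sides = 2))
  wide[is.na(wide)] <- 0
  wide <- as.numeric(wide > 0)
  smooth_k <- rep(1 / (rate_hz + 1), rate_hz + 1)
  sm <- wide
  for (i in 1:2) {
    sm <- as.numeric(stats::filter(sm, smooth_k, sides = 2))
    sm[is.na(sm)] <- 0
  }
  pmin(1, pmax(0, 0.4 + 0.55 * sm + stats::rnorm(n, 0, 0.01)))
}

#' Generate the stimulus-evoked LFP block of a synthetic session
#'
#' A sound-evoked current dipole centered at the channel nearest
#' `sink_depth_um` (400 um, the L3/L4 boundary): each white-noise trial adds
#' a transient (alpha-function time course, peak ~12 ms post onset) with a
#' Gaussian spatial profile, on top of spatially smooth temporally
#' correlated noise. With the noise amplitude at 0 the CSD sink falls on the
#' true channel exactly, and the CSD summed over interior channels is ~0
#' (the dipole conserves current).
#'
#' @param truth A `ground_truth` object from [generate_session()] (or a list
#'   with `trials`, `duration_s`, `channel_depths_um`, `params`).
#' @param seed RNG seed for the noise.
#' @param noise_uv Noise scale override (default from the params in `truth`).
#' @return An [lfp_block()].
#' @export
generate_lfp <- function(truth, seed = 1, noise_uv = NULL) {
  p <- truth$params
  if (is.null(noise_uv)) noise_uv <- p$lfp_noise_uv
  fs <- p$lfp_rate_hz
  chd <- truth$channel_depths_um
  nch <- length(chd)
  n <- ceiling(truth$duration_s * fs)
  g <- exp(-(chd - p$sink_depth_um)^2 / (2 * p$dipole_sigma_um^2))
  tk <- seq(0, 0.15, by = 1 / fs)
  kern <- (tk / p$dipole_tau_s) * exp(1 - tk / p$dipole_tau_s)
  sig <- matrix(0, nch, n)
  wn_onsets <- truth$trials$onset_s[truth$trials$stim == "WN"]
  for (o in wn_onsets) {
    i0 <- round(o * fs) + 1L
    idx <- i0:(i0 + length(kern) - 1L)
    keep <- idx <= n
    sig[, idx[keep]] <- sig[, idx[keep]] + p$dipole_amp_uv * outer(g, kern[keep])
  }
  if (noise_uv > 0) {
    noise <- local_seed(seed, {
      w <- matrix(stats::rnorm(nch * n), nch, n)
      # temporal correlation (AR1) then spatial smoothing across channels
      w <- t(apply(w, 1L, function(x) stats::filter(x, 0.95, method = "recursive")))
      S <- outer(seq_len(nch), seq_len(nch),
                 function(i, j) exp(-(i - j)^2 / (2 * 1.5^2)))
      S <- S / rowSums(S)
      w <- S %*% w
      w / stats::sd(as.numeric(w)) * noise_uv
    })
    sig <- sig + noise
  }
  lfp_block(sig, spacing_um = p$spacing_um, rate_hz = fs)
}

layer_depth_range <- function(layer) {
  lt <- layer_table()
  r <- lt[lt$layer == layer, ]
  c(r$lo_um, r$hi_um)
}

#' Generate a synthetic session with ground truth
#'
#' @param params A [generator_params()] object.
#' @return A list with elements `session` (an `ephys_session`, trial states
#'   unfilled so the analysis pipeline assigns them) and `truth` (class
#'   `ground_truth`): per-unit true depth/layer/class and all rate
#'   parameters plus a `clipped` flag for units whose rate hit the 0 floor;
#'   per-trial true behavioral state; probe geometry, the true sink channel,
#'   and the params used.
#' @export
generate_session <- function(params = generator_params()) {
  p <- params
  period <- 0.6 + 1.0
  n_trials <- 4L * p$n_trials_per_combo

  # --- trial schedule -------------------------------------------------------
  sched <- local_seed(sub_seed(p$seed, "schedule"), {
    combos <- expand.grid(stim = c("WN", "blank"), laser = c("off", "on"),
                          stringsAsFactors = FALSE)
    lab <- combos[rep(seq_len(4), each = p$n_trials_per_combo), ]
    lab[sample.int(n_trials), , drop = FALSE]
  })
  onsets <- 1.0 + (seq_len(n_trials) - 1) * period
  trials <- trial_table(onsets, sched$stim, sched$laser, duration_s = 0.6)
  duration_s <- max(onsets) + period

  # --- running trace and true trial states ---------------------------------
  rt <- local_seed(sub_seed(p$seed, "running"), make_running_trace(duration_s, p))
  running <- behavior_trace(rt$t, rt$speed, p$trace_rate_hz)
  max_speed <- max(rt$speed)
  true_state <- vapply(seq_len(n_trials), function(i) {
    sel <- rt$t >= onsets[i] & rt$t < onsets[i] + 0.6
    if (mean(rt$speed[sel]) > 0.05 * max_speed) "running" else "sitting"
  }, "")

  # --- unit ground truth ----------------------------------------------------
  chd <- p$probe_offset_um + (seq_len(p$n_channels) - 1) * p$spacing_um
  ut <- local_seed(sub_seed(p$seed, "units"), {
    cls <- ifelse(stats::runif(p$n_units) < p$p_ns, "NS", "RS")
    # only layers the probe span actually intersects are populated
    feas <- vapply(names(p$layer_weights), function(L) {
      r <- layer_depth_range(L)
      r[1] <= max(chd) && r[2] >= min(chd)
    }, TRUE)
    w <- p$layer_weights[feas]
    layer <- sample(names(w), p$n_units, replace = TRUE, prob = w)
    depth <- vapply(layer, function(L) {
      r <- layer_depth_range(L)
      lo <- max(r[1], min(chd)); hi <- min(r[2], max(chd))
      stats::runif(1, lo, hi)
    }, 0)
    data.frame(
      unit_id = sprintf("u%03d", seq_len(p$n_units)),
      cell_class = cls, layer = layer, depth_um = depth,
      peak_channel = vapply(depth, function(d) which.min(abs(chd - d)), 0L),
      base_spont_hz = stats::rgamma(p$n_units, p$spont_shape,
                                    scale = p$spont_mean_hz / p$spont_shape),
      onset_gain_hz = stats::rgamma(p$n_units, p$evoked_shape,
                                    scale = p$onset_gain_mean_hz / p$evoked_shape),
      offset_gain_hz = stats::rgamma(p$n_units, p$evoked_shape,
                                     scale = p$offset_gain_mean_hz / p$evoked_shape),
      run_spont_delta_hz = stats::rnorm(
        p$n_units,
        ifelse(cls == "NS", p$run_spont_delta_ns_hz, p$run_spont_delta_rs_hz),
        p$run_spont_sd_hz),
      run_evoked_delta_hz = stats::rnorm(p$n_units, p$run_evoked_delta_hz,
                                         p$run_evoked_sd_hz),
      laser_spont_delta_hz = stats::rnorm(p$n_units, p$laser_spont_delta_hz,
                                          p$laser_spont_sd_hz),
      laser_evoked_delta_hz = stats::rnorm(p$n_units, p$laser_evoked_delta_hz,
                                           p$laser_evoked_sd_hz),
      latency_s = pmax(0.005, stats::rnorm(p$n_units, p$latency_mean_s,
                                           p$latency_sd_s)),
      clipped = FALSE,
      stringsAsFactors = FALSE
    )
  })

  # --- spikes ---------------------------------------------------------------
  is_run <- true_state == "running"
  is_laser <- trials$laser == "on"
  is_wn <- trials$stim == "WN"
  units <- local_seed(sub_seed(p$seed, "spikes"), {
    lapply(seq_len(p$n_units), function(k) {
      u <- ut[k, ]
      lat <- u$latency_s
      # per-trial additive increments (interaction scaling when both active)
      both <- is_run & is_laser
      sc <- ifelse(both, p$interaction_scale, 1)
      spont_add <- sc * (u$run_spont_delta_hz * is_run +
                           u$laser_spont_delta_hz * is_laser)
      spont_add_nolaser <- u$run_spont_delta_hz * is_run
      ev_add <- sc * (u$run_evoked_delta_hz * is_run +
                        u$laser_evoked_delta_hz * is_laser)
      # 6 segments per trial (see header); laser active in segments 1..5
      seg_off <- rbind(-0.05, lat, lat + 0.1, 0.6 + lat, 0.7 + lat, 0.75)
      starts <- rep(onsets, each = 6) + as.numeric(seg_off)
      ends <- rep(onsets, each = 6) +
        as.numeric(rbind(lat, lat + 0.1, 0.6 + lat, 0.7 + lat, 0.75, period - 0.05))
      base <- u$base_spont_hz
      r1 <- base + spont_add
      r2 <- base + spont_add + (u$onset_gain_hz + ev_add) * is_wn
      r4 <- base + spont_add + (u$offset_gain_hz + ev_add) * is_wn
      r6 <- base + spont_add_nolaser
      rates <- as.numeric(rbind(r1, r2, r1, r4, r1, r6))
      clipped <- any(rates < 0)
      rates <- pmax(rates, 0)
      lens <- ends - starts
      cnt <- stats::rpois(length(rates), rates * lens)
      st <- rep(starts, cnt) + stats::runif(sum(cnt)) * rep(lens, cnt)
      ut$clipped[k] <<- clipped
      sort(st)
    })
  })

  # --- waveforms ------------------------------------------------------------
  wfs <- local_seed(sub_seed(p$seed, "waveforms"), {
    lapply(seq_len(p$n_units), function(k) {
      generate_waveform(ut$cell_class[k], seed = NULL, rate_hz = p$wf_rate_hz,
                        channel_depths = chd, depth_um = ut$depth_um[k],
                        amp_uv = p$wf_amp_uv, lambda_um = p$wf_lambda_um)
    })
  })

  unit_objs <- lapply(seq_len(p$n_units), function(k) {
    unit(ut$unit_id[k], units[[k]], waveforms = wfs[[k]],
         waveform_rate_hz = p$wf_rate_hz)
  })

  truth_trials <- as.data.frame(trials)
  truth_trials$state <- true_state
  truth <- structure(list(
    units = ut, trials = truth_trials, duration_s = duration_s,
    channel_depths_um = chd,
    sink_channel_true = which.min(abs(chd - p$sink_depth_um)),
    params = p
  ), class = "ground_truth")

  lfp <- if (p$with_lfp) generate_lfp(truth, seed = sub_seed(p$seed, "lfp")) else NULL
  pupil <- if (p$with_pupil) {
    pv <- local_seed(sub_seed(p$seed, "pupil"),
                     make_pupil_trace(rt$indicator, p$trace_rate_hz))
    behavior_trace(rt$t, pv, p$trace_rate_hz)
  } else NULL

  s <- session(sprintf("synth-%d", p$seed), unit_objs, trials, running,
               pupil = pupil, lfp = lfp, meta = acquisition_meta(),
               duration_s = duration_s)
  list(session = s, truth = truth)
}

#' Generate a population with speed-coupled firing at a known timescale
#'
#' For timescale-recovery analyses: a latent Ornstein-Uhlenbeck process with
#' correlation time `timescale_s` drives both the running-speed trace
#' (rectified latent) and every unit's firing rate (log-linear gain), so the
#' only shared structure between speed and spiking lives at that timescale.
#' With `gain = 0` speed and spiking are independent (null model).
#'
#' @param n_units Number of units.
#' @param duration_s Duration, seconds.
#' @param timescale_s Correlation time of the latent state.
#' @param gain Coupling strength (0 = independent).
#' @param base_hz Mean baseline rate.
#' @param trace_rate_hz Sampling rate of the latent/speed trace.
#' @param seed RNG seed.
#' @return List with `units` (spike-time vectors), `speed`
#'   ([behavior_trace()]), `duration_s` and `truth`.
#' @export
generate_coupled_population <- function(n_units = 20, duration_s = 240,
                                        timescale_s = 0.4, gain = 1,
                                        base_hz = 5, trace_rate_hz = 50,
                                        seed = 1) {
  local_seed(seed, {
    dt <- 1 / trace_rate_hz
    n <- ceiling(duration_s * trace_rate_hz)
    phi <- exp(-dt / timescale_s)
    z <- as.numeric(stats::filter(stats::rnorm(n, 0, sqrt(1 - phi^2)), phi,
                                  method = "recursive", init = stats::rnorm(1)))
    speed <- pmax(z, 0) * 4
    g <- gain * stats::runif(n_units, 0.5, 1.5)
    b <- base_hz * stats::runif(n_units, 0.6, 1.6)
    t0 <- (seq_len(n) - 1) * dt
    units <- lapply(seq_len(n_units), function(i) {
      lam <- b[i] * exp(g[i] * z - g[i]^2 / 2) * dt
      cnt <- stats::rpois(n, lam)
      sort(rep(t0, cnt) + stats::runif(sum(cnt)) * dt)
    })
    list(units = units,
         speed = behavior_trace(t0, speed, trace_rate_hz),
         duration_s = duration_s,
         truth = list(timescale_s = timescale_s, gains = g, base_hz = b, z = z))
  })
}
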