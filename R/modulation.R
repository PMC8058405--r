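# Sound modulation index and the running/laser effect decomposition.
#
# MI = (E - S) / (E + S) with E the mean evoked onset rate (WN trials) and S
# the mean spontaneous rate on interleaved blanks over the matched window,
# computed per unit in each of the four state x laser conditions. Units enter
# the MI analysis only if they respond to sound with a significant *increase*
# on sitting laser-off trials, so MI_sitting_laser-off lies in [0, 1]; the
# other condition MIs may fall anywhere in [-1, 1].

#' Sound modulation index
#'
#' `(E - S) / (E + S)` for mean evoked rate `E` and mean spontaneous rate
#' `S`; 1 = purely sound-driven, 0 = no modulation, -1 = fully suppressed by
#' sound. Undefined (NA) when both rates are 0.
#'
#' @param evoked_hz Mean evoked firing rate, Hz (>= 0).
#' @param spont_hz Mean spontaneous firing rate, Hz (>= 0).
#' @return MI in \[-1, 1\], or `NA` when `E = S = 0`.
#' @export
sound_mi <- function(evoked_hz, spont_hz) {
  stopifnot(all(evoked_hz >= 0, na.rm = TRUE), all(spont_hz >= 0, na.rm = TRUE))
  tot <- evoked_hz + spont_hz
  out <- ifelse(tot > 0, (evoked_hz - spont_hz) / tot, NA_real_)
  out
}

#' Condition-specific sound MI for one unit
#'
#' Evoked rate: mean onset-window (0-100 ms) rate over WN trials of the
#' condition. Spontaneous rate: mean rate over the full stimulus-equivalent
#' window of the condition's interleaved blank trials (silent periods
#' matching the stimulus duration and presentation intervals). Returns `NA`
#' with a reason when either trial count is below `min_trials`.
#'
#' @param u A [unit()].
#' @param trials A labelled [trial_table()].
#' @param state `"sitting"` or `"running"`.
#' @param laser `"off"` or `"on"`.
#' @param window Evoked analysis window relative to onset, seconds.
#' @param spont_window Spontaneous window applied to blank trials (default
#'   the full 600 ms stimulus-equivalent period).
#' @param min_trials Minimum WN and blank trial count (default 7, the same
#'   floor as the running-trial inclusion rule).
#' @return List with `mi`, `evoked_hz`, `spont_hz`, `n_wn`, `n_blank`,
#'   `reason` (`NA` unless undefined).
#' @export
condition_mi <- function(u, trials, state, laser, window = c(0, 0.1),
                         spont_window = c(0, 0.6), min_trials = 7) {
  wn <- select_trials(trials, "WN", laser, state)
  bl <- select_trials(trials, "blank", laser, state)
  if (nrow(wn) < min_trials || nrow(bl) < min_trials) {
    return(list(mi = NA_real_, evoked_hz = NA_real_, spont_hz = NA_real_,
                n_wn = nrow(wn), n_blank = nrow(bl),
                reason = "insufficient trials"))
  }
  e <- mean(trial_rates(u, wn, window))
  s0 <- mean(trial_rates(u, bl, spont_window))
  mi <- sound_mi(e, s0)
  list(mi = mi, evoked_hz = e, spont_hz = s0, n_wn = nrow(wn),
       n_blank = nrow(bl),
       reason = if (is.na(mi)) "zero evoked and spontaneous rates" else NA_character_)
}

#' Effect decomposition from the four condition MIs
#'
#' Running effect = MI(running, laser-off) - MI(sitting, laser-off);
#' VIP (laser) effect = MI(sitting, laser-on) - MI(sitting, laser-off);
#' predicted combined effect = running effect + VIP effect (linear
#' additivity); observed combined effect = MI(running, laser-on) -
#' MI(sitting, laser-off). Any effect whose inputs are undefined is `NA`.
#'
#' @param mi_sit_off,mi_run_off,mi_sit_on,mi_run_on Condition MIs.
#' @return List with `running_effect`, `vip_effect`, `predicted_combined`,
#'   `observed_combined`.
#' @export
effects <- function(mi_sit_off, mi_run_off, mi_sit_on, mi_run_on) {
  running_effect <- mi_run_off - mi_sit_off
  vip_effect <- mi_sit_on - mi_sit_off
  list(running_effect = running_effect,
       vip_effect = vip_effect,
       predicted_combined = running_effect + vip_effect,
       observed_combined = mi_run_on - mi_sit_off)
}

#' Per-unit modulation table for a session
#'
#' Computes the four condition MIs and the derived effects for every unit
#' that passes the sound-responsiveness (significant increase) criterion,
#' plus the normalized laser effects on evoked and spontaneous activity.
#'
#' @param s A labelled, classified `ephys_session`.
#' @param min_trials Minimum trials per condition for an MI to be defined.
#' @param alpha Significance level for the inclusion test.
#' @return A `data.frame` of class `modulation_set`, one row per included
#'   unit: `unit_id`, `layer`, `cell_class`, `mi_sit_off`, `mi_run_off`,
#'   `mi_sit_on`, `mi_run_on`, `running_effect`, `vip_effect`,
#'   `predicted_combined`, `observed_combined`, `laser_effect_evoked_norm`,
#'   `laser_effect_spont_norm`.
#' @export
modulation_set <- function(s, min_trials = 7, alpha = 0.01) {
  stopifnot(!any(s$trials$state == "unfilled"))
  rows <- list()
  for (u in s$units) {
    sig <- tryCatch(significant_evoked(u, s$trials, alpha = alpha),
                    error = function(e) list(sig_increase = FALSE))
    if (!isTRUE(sig$sig_increase)) next
    m_so <- condition_mi(u, s$trials, "sitting", "off", min_trials = min_trials)
    m_ro <- condition_mi(u, s$trials, "running", "off", min_trials = min_trials)
    m_sn <- condition_mi(u, s$trials, "sitting", "on", min_trials = min_trials)
    m_rn <- condition_mi(u, s$trials, "running", "on", min_trials = min_trials)
    ef <- effects(m_so$mi, m_ro$mi, m_sn$mi, m_rn$mi)
    le <- tryCatch(laser_effect_norm(u, s$trials, s$meta),
                   error = function(e) list(evoked_norm = NA_real_,
                                            spont_norm = NA_real_))
    rows[[length(rows) + 1L]] <- data.frame(
      unit_id = u$unit_id, layer = u$layer, cell_class = u$cell_class,
      mi_sit_off = m_so$mi, mi_run_off = m_ro$mi, mi_sit_on = m_sn$mi,
      mi_run_on = m_rn$mi,
      running_effect = ef$running_effect, vip_effect = ef$vip_effect,
      predicted_combined = ef$predicted_combined,
      observed_combined = ef$observed_combined,
      laser_effect_evoked_norm = le$evoked_norm,
      laser_effect_spont_norm = le$spont_norm,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(unit_id = character(), layer = character(),
               cell_class = character(), mi_sit_off = numeric(),
               mi_run_off = numeric(), mi_sit_on = numeric(),
               mi_run_on = numeric(), running_effect = numeric(),
               vip_effect = numeric(), predicted_combined = numeric(),
               observed_combined = numeric(),
               laser_effect_evoked_norm = numeric(),
               laser_effect_spont_norm = numeric(), stringsAsFactors = FALSE)
  class(out) <- c("modulation_set", "data.frame")
  out
}

#' Linear-additivity (interaction) test across the population
#'
#' Tests whether the observed combined effect of running plus laser equals
#' the arithmetic sum of the two effects measured separately. Reports the
#' Spearman rank correlation between predicted and observed effects, the
#' ordinary least-squares fit `observed ~ predicted` (slope 1 / intercept 0
#' under exact additivity; slope below 1 indicates a sub-additive
#' interaction), and single-predictor comparison fits against the running
#' and laser effects alone.
#'
#' @param mods A `modulation_set` (or data.frame with `predicted_combined`,
#'   `observed_combined`, `running_effect`, `vip_effect`).
#' @return List of class `additivity_test` with `rho`, `p`, `slope`,
#'   `intercept`, `r2`, `n`, `mean_diff`, `se_diff`, `r2_running_only`,
#'   `r2_vip_only`.
#' @export
additivity_test <- function(mods) {
  ok <- stats::complete.cases(mods[, c("predicted_combined", "observed_combined")])
  d <- mods[ok, , drop = FALSE]
  if (nrow(d) < 3) stop("additivity test needs >=3 units with defined effects")
  ct <- suppressWarnings(stats::cor.test(d$predicted_combined,
                                         d$observed_combined,
                                         method = "spearman"))
  fit <- stats::lm(observed_combined ~ predicted_combined, data = d)
  r2_of <- function(form) {
    dd <- d[stats::complete.cases(d[, all.vars(form)]), , drop = FALSE]
    if (nrow(dd) < 3) return(NA_real_)
    summary(stats::lm(form, data = dd))$r.squared
  }
  diff <- d$observed_combined - d$predicted_combined
  structure(list(
    rho = unname(ct$estimate), p = ct$p.value,
    slope = unname(stats::coef(fit)[2]), intercept = unname(stats::coef(fit)[1]),
    slope_se = summary(fit)$coefficients[2, 2],
    r2 = summary(fit)$r.squared, n = nrow(d),
    mean_diff = mean(diff), se_diff = stats::sd(diff) / sqrt(length(diff)),
    r2_running_only = r2_of(observed_combined ~ running_effect),
    r2_vip_only = r2_of(observed_combined ~ vip_effect)
  ), class = "additivity_test")
}

#' Sitting-trial subsampling matched to the running-trial count
#'
#' Running trials are typically far fewer than sitting trials. To rule out a
#' trial-count artifact in the sitting-vs-running MI comparison, this draws
#' `n_running` sitting laser-off trials (without replacement) `n_repeats`
#' times, recomputes each unit's sitting MI from the subsample, and compares
#' the population MI against the running MI with a paired signed-rank test
#' per repeat.
#'
#' @param s A labelled `ephys_session`.
#' @param n_repeats Number of random subsamples (default 100).
#' @param seed RNG seed for the subsampling stream (independent of any
#'   generator seed).
#' @param min_trials Minimum WN/blank counts within a subsample for a unit's
#'   MI to be defined.
#' @param alpha Inclusion-test level.
#' @return List of class `subsample_result`: `mean_mi_per_repeat`,
#'   `p_per_repeat`, `mean_mi` (grand mean), `sem_mi`, `range_mi`,
#'   `mean_p`, `running_mean_mi`, `n_running`, `n_repeats`.
#' @export
matched_subsample_mi <- function(s, n_repeats = 100, seed = 1, min_trials = 2,
                                 alpha = 0.01) {
  stopifnot(!any(s$trials$state == "unfilled"))
  run_off <- which(s$trials$state == "running" & s$trials$laser == "off")
  sit_off <- which(s$trials$state == "sitting" & s$trials$laser == "off")
  n_running <- length(run_off)
  if (length(sit_off) < n_running) stop("fewer sitting than running trials")
  included <- Filter(function(u) {
    isTRUE(tryCatch(significant_evoked(u, s$trials, alpha = alpha)$sig_increase,
                    error = function(e) FALSE))
  }, s$units)
  if (!length(included)) stop("no sound-responsive units for subsampling")
  unit_mi <- function(u, idx) {
    tt <- s$trials[idx, , drop = FALSE]
    wn <- tt[tt$stim == "WN", , drop = FALSE]
    bl <- tt[tt$stim == "blank", , drop = FALSE]
    if (nrow(wn) < min_trials || nrow(bl) < min_trials) return(NA_real_)
    sound_mi(mean(trial_rates(u, wn, c(0, 0.1))),
             mean(trial_rates(u, bl, c(0, 0.6))))
  }
  run_mi <- vapply(included, unit_mi, 0, idx = run_off)
  res <- local_seed(seed, {
    means <- numeric(n_repeats)
    pvals <- numeric(n_repeats)
    for (r in seq_len(n_repeats)) {
      draw <- if (length(sit_off) == n_running) sit_off else
        sample(sit_off, n_running)
      sit_mi <- vapply(included, unit_mi, 0, idx = draw)
      means[r] <- mean(sit_mi, na.rm = TRUE)
      pair <- stats::complete.cases(sit_mi, run_mi)
      pvals[r] <- if (sum(pair) >= 3) {
        suppressWarnings(stats::wilcox.test(sit_mi[pair], run_mi[pair],
                                            paired = TRUE)$p.value)
      } else NA_real_
    }
    list(means = means, pvals = pvals)
  })
  structure(list(
    mean_mi_per_repeat = res$means, p_per_repeat = res$pvals,
    mean_mi = mean(res$means), sem_mi = stats::sd(res$means) / sqrt(n_repeats),
    range_mi = range(res$means), mean_p = mean(res$pvals, na.rm = TRUE),
    running_mean_mi = mean(run_mi, na.rm = TRUE),
    n_running = n_running, n_repeats = n_repeats
  ), class = "subsample_result")
}

#' Normalized laser effect on evoked and spontaneous activity
#'
#' The difference between laser-on and laser-off mean rates (sitting trials
#' only), normalized to the unit's peak laser-off firing rate (from the 5 ms
#' PSTH over sitting laser-off WN trials). Evoked uses the onset window on WN
#' trials; spontaneous uses the full stimulus-equivalent window on blanks.
#'
#' @param u A [unit()].
#' @param trials A labelled [trial_table()].
#' @param meta [acquisition_meta()] (for the stimulus duration).
#' @return List with `evoked_norm`, `spont_norm`, `peak_hz`; values `NA`
#'   when the laser-off peak is not positive.
#' @export
laser_effect_norm <- function(u, trials, meta = acquisition_meta()) {
  dur <- meta$stim_dur_s
  sel <- function(stim, laser) select_trials(trials, stim, laser, "sitting")
  wn_off <- sel("WN", "off"); wn_on <- sel("WN", "on")
  bl_off <- sel("blank", "off"); bl_on <- sel("blank", "on")
  if (!nrow(wn_off) || !nrow(wn_on) || !nrow(bl_off) || !nrow(bl_on)) {
    stop("missing sitting trials for laser-effect computation")
  }
  pk <- max(psth(u, wn_off, range = c(0, dur + 0.1), bin_s = 0.005)$rate_hz)
  if (!is.finite(pk) || pk <= 0) {
    return(list(evoked_norm = NA_real_, spont_norm = NA_real_, peak_hz = pk))
  }
  ev <- (mean(trial_rates(u, wn_on, c(0, 0.1))) -
           mean(trial_rates(u, wn_off, c(0, 0.1)))) / pk
  sp <- (mean(trial_rates(u, bl_on, c(0, dur))) -
           mean(trial_rates(u, bl_off, c(0, dur)))) / pk
  list(evoked_norm = ev, spont_norm = sp, peak_hz = pk)
}
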