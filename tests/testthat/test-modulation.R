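test_that("the modulation index follows (E - S) / (E + S)", {
  expect_equal(sound_mi(7, 7), 0)
  expect_equal(sound_mi(10, 0), 1)
  expect_equal(sound_mi(0, 10), -1)
  expect_equal(sound_mi(10, 5), 1 / 3)
  expect_true(is.na(sound_mi(0, 0)))
  expect_error(sound_mi(-1, 2))
})

test_that("MI stays in [-1, 1] over random nonnegative rate pairs", {
  set.seed(3)
  e <- rgamma(500, 1, scale = 10)
  s <- rgamma(500, 1, scale = 10)
  mi <- sound_mi(e, s)
  expect_true(all(mi >= -1 & mi <= 1, na.rm = TRUE))
})

test_that("effects are the published differences and sums of condition MIs", {
  ef <- effects(0.5, 0.2, 0.4, 0.1)
  expect_equal(ef$running_effect, -0.3)
  expect_equal(ef$vip_effect, -0.1)
  expect_equal(ef$predicted_combined, -0.4)
  expect_equal(ef$observed_combined, -0.4)

  ef2 <- effects(0.3, 0.3, 0.3, 0.3)
  expect_true(all(unlist(ef2) == 0))

  ef3 <- effects(0.5, NA, 0.4, 0.1)
  expect_true(is.na(ef3$running_effect) && is.na(ef3$predicted_combined))
  expect_equal(ef3$vip_effect, -0.1)
})

test_that("condition MI reports a reason when trials are insufficient", {
  tt <- trial_table(c(1, 2.6), c("WN", "blank"), c("off", "off"))
  tt$state <- "sitting"
  u <- unit("u", c(1.01, 1.02))
  r <- condition_mi(u, tt, "sitting", "off", min_trials = 7)
  expect_true(is.na(r$mi))
  expect_match(r$reason, "insufficient")
  r2 <- condition_mi(u, tt, "sitting", "off", min_trials = 1)
  expect_equal(r2$mi, 1)  # evoked 20 Hz, spont 0
})

test_that("units without a significant evoked increase are excluded from the MI set", {
  g <- generate_session(generator_params(n_units = 25, n_trials_per_combo = 40,
                                         seed = 19, with_lfp = FALSE,
                                         with_pupil = FALSE))
  s <- label_session(g$session)
  mods <- modulation_set(s, min_trials = 2)
  sig_ids <- vapply(s$units, function(u) {
    if (isTRUE(significant_evoked(u, s$trials)$sig_increase)) u$unit_id else NA_character_
  }, "")
  expect_setequal(mods$unit_id, sig_ids[!is.na(sig_ids)])
  # increase-only inclusion bounds the sitting laser-off MI to [0, 1]
  expect_true(all(mods$mi_sit_off >= 0 & mods$mi_sit_off <= 1, na.rm = TRUE))
  expect_true(all(abs(mods$running_effect) <= 2, na.rm = TRUE))
  expect_true(all(abs(mods$predicted_combined) <= 4, na.rm = TRUE))
})

test_that("running deltas of opposite sign force the MI to drop during running", {
  g <- generate_session(generator_params(
    n_units = 30, n_trials_per_combo = 60, seed = 23, with_lfp = FALSE,
    with_pupil = FALSE,
    run_spont_delta_rs_hz = 4, run_spont_delta_ns_hz = 4, run_spont_sd_hz = 0,
    run_evoked_delta_hz = -8, run_evoked_sd_hz = 0,
    mean_run_bout_s = 20, mean_sit_bout_s = 20))
  s <- label_session(g$session)
  mods <- modulation_set(s, min_trials = 5)
  ok <- stats::complete.cases(mods$mi_run_off, mods$mi_sit_off)
  expect_gt(sum(ok), 5)
  expect_gt(mean(mods$mi_run_off[ok] < mods$mi_sit_off[ok]), 0.9)
})

test_that("additivity test returns identity statistics when observed equals predicted", {
  set.seed(11)
  pred <- rnorm(30)
  mods <- data.frame(predicted_combined = pred, observed_combined = pred,
                     running_effect = pred / 2, vip_effect = pred / 2)
  at <- suppressWarnings(additivity_test(mods))  # exact fit warns in summary.lm
  expect_equal(at$rho, 1)
  expect_equal(at$slope, 1)
  expect_equal(at$intercept, 0)
  expect_equal(at$r2, 1)
  expect_equal(at$n, 30)
  expect_error(additivity_test(mods[1:2, ]), ">=3")
})

test_that("matched subsampling is degenerate when counts match, deterministic under a seed", {
  g <- generate_session(generator_params(
    n_units = 15, n_trials_per_combo = 40, seed = 29, with_lfp = FALSE,
    with_pupil = FALSE, mean_run_bout_s = 20, mean_sit_bout_s = 20))
  s <- label_session(g$session)
  r1 <- matched_subsample_mi(s, n_repeats = 20, seed = 5)
  r2 <- matched_subsample_mi(s, n_repeats = 20, seed = 5)
  expect_identical(r1, r2)
  r3 <- matched_subsample_mi(s, n_repeats = 20, seed = 6)
  expect_false(identical(r1$mean_mi_per_repeat, r3$mean_mi_per_repeat))
  # subsampled sitting means bracket the direction of the full-data comparison
  expect_true(all(is.finite(r1$mean_mi_per_repeat)))

  # equal counts: every repeat uses all sitting trials
  tt <- s$trials
  run_idx <- which(tt$state == "running" & tt$laser == "off")
  sit_idx <- which(tt$state == "sitting" & tt$laser == "off")
  keep <- c(run_idx, sit_idx[seq_along(run_idx)],
            which(tt$laser == "on"))
  s2 <- s
  s2$trials <- tt[sort(keep), , drop = FALSE]
  r4 <- matched_subsample_mi(s2, n_repeats = 10, seed = 1)
  expect_equal(length(unique(round(r4$mean_mi_per_repeat, 12))), 1)
})

test_that("the normalized laser effect matches direct arithmetic and is scale invariant", {
  onsets <- 1 + (0:39) * 1.6
  stim <- rep(c("WN", "blank"), 20)
  laser <- rep(c("off", "off", "on", "on"), 10)
  tt <- trial_table(onsets, stim, laser)
  tt$state <- "sitting"
  wn_off <- onsets[stim == "WN" & laser == "off"]
  wn_on <- onsets[stim == "WN" & laser == "on"]
  # laser-off: 1 onset spike per trial spread over distinct 5 ms bins (20 Hz
  # onset rate); a concentrated late bin sets the PSTH peak to 40 Hz
  n_off <- length(wn_off)
  st <- c(
    spikes_at_each(wn_off, 0.005 * (seq_len(n_off) - 1) + 0.0025),
    rep(wn_off[1] + 0.3025, 2),
    spikes_at_each(wn_on, 0.005 * (seq_len(n_off) - 1) + 0.0025),
    spikes_at_each(wn_on, 0.005 * (seq_len(n_off) - 1) + 0.05 + 0.0025)
  )
  u <- unit("l", sort(st))
  le <- laser_effect_norm(u, tt)
  expect_equal(le$peak_hz, 40)
  expect_equal(le$evoked_norm, (20 - 10) / 40)
  expect_equal(le$spont_norm, 0)

  # duplicating every spike scales all rates but not the normalized effect
  u2 <- unit("l2", sort(rep(u$spike_times, 3)))
  le2 <- laser_effect_norm(u2, tt)
  expect_equal(le2$evoked_norm, le$evoked_norm)

  # laser-on == laser-off gives a zero effect
  st_eq <- c(spikes_at_each(wn_off, 0.0125), spikes_at_each(wn_on, 0.0125))
  le3 <- laser_effect_norm(unit("l3", sort(st_eq)), tt)
  expect_equal(le3$evoked_norm, 0)
})
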