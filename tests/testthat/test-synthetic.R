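test_that("the same seed generates identical sessions", {
  p <- generator_params(n_units = 5, n_trials_per_combo = 4, seed = 77,
                        n_channels = 6, lfp_rate_hz = 250, trace_rate_hz = 50)
  g1 <- generate_session(p)
  g2 <- generate_session(p)
  expect_identical(g1$truth$units, g2$truth$units)
  for (i in 1:5) {
    expect_identical(g1$session$units[[i]]$spike_times,
                     g2$session$units[[i]]$spike_times)
  }
  expect_identical(g1$session$lfp$data, g2$session$lfp$data)
  expect_identical(g1$session$running$v, g2$session$running$v)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_session(g1$session, d1)
  write_session(g2$session, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("the trial schedule interleaves the four combinations at the requested count", {
  g <- generate_session(generator_params(n_units = 1, n_trials_per_combo = 30,
                                         seed = 2, with_lfp = FALSE,
                                         with_pupil = FALSE))
  tt <- g$session$trials
  expect_equal(nrow(tt), 120)
  expect_true(all(table(tt$stim, tt$laser) == 30))
  expect_equal(diff(tt$onset_s), rep(1.6, 119))
  expect_length(validate_session(g$session), 0)
})

test_that("with all deltas zero, MI is unchanged by state and laser", {
  g <- generate_session(generator_params(
    n_units = 50, n_trials_per_combo = 200, seed = 41,
    run_spont_delta_rs_hz = 0, run_spont_delta_ns_hz = 0, run_spont_sd_hz = 0,
    run_evoked_delta_hz = 0, run_evoked_sd_hz = 0,
    laser_spont_delta_hz = 0, laser_spont_sd_hz = 0,
    laser_evoked_delta_hz = 0, laser_evoked_sd_hz = 0,
    with_lfp = FALSE, with_pupil = FALSE))
  s <- label_session(g$session)
  mods <- modulation_set(s, min_trials = 7)
  d_run <- mean(mods$mi_run_off - mods$mi_sit_off, na.rm = TRUE)
  d_las <- mean(mods$mi_sit_on - mods$mi_sit_off, na.rm = TRUE)
  expect_lt(abs(d_run), 0.05)
  expect_lt(abs(d_las), 0.05)
})

test_that("default calibration reproduces the target population firing rates", {
  g <- generate_session(generator_params(n_units = 235, seed = 1,
                                         with_lfp = FALSE))
  s <- label_session(g$session)
  expect_gte(sum(s$trials$state == "running"), 7)
  resp <- response_summary(s, min_trials = 1)
  so <- resp[resp$state == "sitting" & resp$laser == "off", ]
  ro <- resp[resp$state == "running" & resp$laser == "off", ]
  # population means within 2 published SEMs of the published means
  expect_lt(abs(mean(so$spont_hz, na.rm = TRUE) - 4.87), 2 * 0.32)
  expect_lt(abs(mean(ro$spont_hz, na.rm = TRUE) - 6.50), 2 * 0.38)
  expect_lt(abs(mean(so$onset_hz, na.rm = TRUE) - 15.81), 2 * 1.18)
  expect_lt(abs(mean(ro$onset_hz, na.rm = TRUE) - 13.97), 2 * 1.09)
})

test_that("running bouts produce a minority of running trials at realistic speeds", {
  fr <- vapply(1:4, function(sd) {
    g <- generate_session(generator_params(n_units = 1, seed = sd,
                                           with_lfp = FALSE, with_pupil = FALSE))
    s <- label_session(g$session)
    run <- s$trials$state == "running"
    c(mean(run), mean(s$trials$mean_speed[run]))
  }, c(0, 0))
  expect_gt(mean(fr[1, ]), 0.05)
  expect_lt(mean(fr[1, ]), 0.30)
  expect_gt(mean(fr[2, ], na.rm = TRUE), 4)   # cm/s on running trials
})

test_that("clipped units are flagged in the ground truth", {
  g <- generate_session(generator_params(
    n_units = 20, n_trials_per_combo = 5, seed = 3,
    run_evoked_delta_hz = -60, run_evoked_sd_hz = 0,
    with_lfp = FALSE, with_pupil = FALSE))
  expect_true(any(g$truth$units$clipped))
})

test_that("parameter recovery: estimated spontaneous running deltas are unbiased", {
  g <- generate_session(generator_params(
    n_units = 60, n_trials_per_combo = 200, seed = 55,
    mean_run_bout_s = 20, mean_sit_bout_s = 20,
    with_lfp = FALSE, with_pupil = FALSE))
  s <- label_session(g$session)
  resp <- response_summary(s, min_trials = 10)
  so <- resp[resp$state == "sitting" & resp$laser == "off", ]
  ro <- resp[resp$state == "running" & resp$laser == "off", ]
  est <- ro$spont_hz - so$spont_hz
  truth <- g$truth$units$run_spont_delta_hz[!g$truth$units$clipped]
  err <- est[!g$truth$units$clipped] - truth
  err <- err[!is.na(err)]
  se <- sd(err) / sqrt(length(err))
  expect_lt(abs(mean(err)), 2 * se + 1e-9)
})
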