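test_that("trial rates count spikes in half-open windows", {
  tt <- trial_table(c(2, 10), c("WN", "WN"), c("off", "off"))
  u <- unit("a", c(2.05, 2.25, 10.05, 10.25))
  expect_equal(trial_rates(u, tt, c(0, 0.1)), c(10, 10))
  # spike exactly at the window end is excluded, at the start included
  u2 <- unit("b", c(2.0, 2.1))
  expect_equal(trial_rates(u2, tt, c(0, 0.1)), c(10, 0))
  u3 <- unit("c", numeric(0))
  expect_equal(trial_rates(u3, tt, c(0, 0.1)), c(0, 0))
})

test_that("empty trial selections raise an error naming the unit", {
  tt <- trial_table(2, "WN", "off")
  expect_error(trial_rates(unit("u9", 1), tt[tt$stim == "blank", ], c(0, 0.1)),
               "u9")
})

test_that("mean rate over many Poisson trials approaches the true rate", {
  set.seed(5)
  onsets <- (1:200) * 2
  st <- sort(unlist(lapply(onsets, function(o) o + sort(runif(rpois(1, 2), 0, 0.1)))))
  u <- unit("p", st)
  tt <- trial_table(onsets, rep("WN", 200), rep("off", 200))
  r <- trial_rates(u, tt, c(0, 0.1))
  se <- sqrt(20 / (0.1 * 200))
  expect_lt(abs(mean(r) - 20), 3 * se)
})

test_that("rates are additive across adjacent windows", {
  set.seed(8)
  onsets <- (1:30) * 2
  st <- sort(runif(500, 0, 61))
  u <- unit("w", st)
  tt <- trial_table(onsets, rep("WN", 30), rep("off", 30))
  r_full <- trial_rates(u, tt, c(0, 0.1))
  r_a <- trial_rates(u, tt, c(0, 0.05))
  r_b <- trial_rates(u, tt, c(0.05, 0.1))
  expect_equal(r_full, (r_a + r_b) / 2)
})

test_that("evoked significance requires an increase, not just a difference", {
  onsets <- 1 + (0:59) * 1.6
  stim <- rep(c("WN", "blank"), 30)
  tt <- trial_table(onsets, stim, rep("off", 60))
  tt$state <- "sitting"
  wn_on <- onsets[stim == "WN"]
  bl_on <- onsets[stim == "blank"]

  driven <- unit("d", spikes_at(wn_on, c(0.01, 0.03, 0.05)))
  r <- significant_evoked(driven, tt)
  expect_true(r$sig_increase)
  expect_lt(r$p, 0.01)

  suppressed <- unit("s", spikes_at(bl_on, c(0.01, 0.03, 0.05)))
  r2 <- significant_evoked(suppressed, tt)
  expect_false(r2$sig_increase)
  expect_lt(r2$p, 0.01)  # significant, but a decrease

  flat <- unit("f", spikes_at(onsets, 0.05))
  r3 <- significant_evoked(flat, tt)
  expect_false(r3$sig_increase)
  expect_gt(r3$p, 0.9)
})

test_that("latency of a step response is the step time, with interpolation", {
  onsets <- 1 + (0:19) * 2
  tt <- trial_table(onsets, rep("WN", 20), rep("off", 20))
  # no spikes before 20 ms, then 1 spike per ms per trial
  offs <- seq(0.020, 0.1995, by = 0.001)
  u <- unit("step", spikes_at(onsets, offs))
  lat <- response_latency(u, tt)
  expect_lt(abs(lat - 0.020), 0.001)
})

test_that("latency of a linear ramp is at half the ramp duration", {
  onsets <- 1 + (0:9) * 2
  # spike count per 5 ms bin proportional to bin index, ramp extending past
  # the search window so smoothing does not clip the peak
  offs <- unlist(lapply(1:21, function(i) {
    (i - 1) * 0.005 + seq(0.0005, 0.0045, length.out = i)
  }))
  u <- unit("ramp", spikes_at(onsets, offs))
  lat <- response_latency(u, trial_table(onsets, rep("WN", 10), rep("off", 10)),
                          search = c(0, 0.1))
  expect_lt(abs(lat - 0.050), 0.005)
})

test_that("delaying all spikes shifts latency by the same amount", {
  onsets <- 1 + (0:19) * 2
  tt <- trial_table(onsets, rep("WN", 20), rep("off", 20))
  offs <- seq(0.020, 0.120, by = 0.002)
  u <- unit("a", spikes_at(onsets, offs))
  u_shift <- unit("b", u$spike_times + 0.030)
  l1 <- response_latency(u, tt)
  l2 <- response_latency(u_shift, tt)
  expect_lt(abs((l2 - l1) - 0.030), 0.005)
})

test_that("latency is undefined when the PSTH peak is zero", {
  tt <- trial_table(c(1, 3), c("WN", "WN"), c("off", "off"))
  expect_true(is.na(response_latency(unit("z", numeric(0)), tt)))
})

test_that("generator latency differences are recovered from PSTHs", {
  lat_of <- function(mean_lat, seed) {
    g <- generate_session(generator_params(
      n_units = 50, n_trials_per_combo = 30, seed = seed, with_lfp = FALSE,
      with_pupil = FALSE, latency_mean_s = mean_lat, latency_sd_s = 0))
    s <- label_session(g$session)
    wn <- select_trials(s$trials, "WN", "off", "sitting")
    mean(vapply(s$units, function(u) response_latency(u, wn), 0), na.rm = TRUE)
  }
  d <- lat_of(0.025, 31) - lat_of(0.015, 32)
  expect_lt(abs(d - 0.010), 0.005)
})

test_that("offset windows track the stimulus duration from the metadata", {
  g <- generate_session(generator_params(n_units = 10, n_trials_per_combo = 20,
                                         seed = 17, with_lfp = FALSE,
                                         with_pupil = FALSE))
  s <- label_session(g$session)
  resp <- response_summary(s, min_trials = 2)
  so <- resp[resp$state == "sitting" & resp$laser == "off", ]
  truth <- g$truth$units
  # offset rates exceed spontaneous rates for units with substantial offset gain
  big <- truth$offset_gain_hz > 5
  expect_true(mean(so$offset_hz[big] > so$spont_hz[big]) > 0.8)
})
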