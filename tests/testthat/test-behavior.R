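test_that("moving-median smoothing is idempotent on constants and kills single-sample artifacts", {
  tr <- behavior_trace(seq(0, 1, 0.01), rep(3.5, 101), 100)
  expect_equal(smooth_running(tr)$v, tr$v)

  v <- rep(0, 101); v[50] <- 40
  tr2 <- behavior_trace(seq(0, 1, 0.01), v, 100)
  expect_equal(smooth_running(tr2)$v, rep(0, 101))
})

test_that("moving median matches a brute-force per-window median on a ramp", {
  n <- 60
  tr <- behavior_trace((0:(n - 1)) / 100, as.numeric(0:(n - 1)), 100)
  sm <- smooth_running(tr, window_s = 0.05)  # 5 samples
  k <- 5; h <- (k - 1) / 2
  interior <- (h + 1):(n - h)
  brute <- vapply(interior, function(i) stats::median(tr$v[(i - h):(i + h)]), 0)
  expect_equal(sm$v[interior], brute)
  # interior of a monotone ramp is unchanged by a median filter
  expect_equal(sm$v[interior], tr$v[interior])
})

test_that("trials are labelled by the 5%-of-max rule with strict inequality", {
  # speed 20 cm/s for a stretch (sets max), then per-trial plateaus 0, 0.5, 2
  t <- seq(0, 12, 0.01)
  v <- numeric(length(t))
  v[t >= 10] <- 20
  trial_means <- c(0, 0.5, 2.0)
  onsets <- c(1, 3, 5)
  for (i in 1:3) v[t >= onsets[i] & t < onsets[i] + 0.6] <- trial_means[i]
  tt <- trial_table(onsets, rep("WN", 3), rep("off", 3))
  lab <- label_trials(tt, behavior_trace(t, v, 100))
  expect_equal(lab$max_speed, 20)
  expect_equal(lab$trials$state, c("sitting", "sitting", "running"))
  expect_equal(lab$trials$mean_speed, trial_means)
})

test_that("sessions need at least 7 running trials to be included", {
  t <- seq(0, 40, 0.02)
  onsets <- 1 + (0:11) * 1.6
  v <- rep(0.01, length(t))
  run_trials <- 1:6
  for (i in run_trials) v[t >= onsets[i] & t < onsets[i] + 0.6] <- 10
  tt <- trial_table(onsets, rep("WN", 12), rep("off", 12))
  lab <- label_trials(tt, behavior_trace(t, v, 50))
  expect_equal(lab$n_running, 6)
  expect_false(lab$included)

  for (i in 7) v[t >= onsets[i] & t < onsets[i] + 0.6] <- 10
  lab2 <- label_trials(tt, behavior_trace(t, v, 50))
  expect_equal(lab2$n_running, 7)
  expect_true(lab2$included)
})

test_that("an all-zero speed trace yields all sitting and exclusion", {
  t <- seq(0, 10, 0.02)
  tt <- trial_table(c(1, 3), c("WN", "blank"), c("off", "off"))
  lab <- label_trials(tt, behavior_trace(t, rep(0, length(t)), 50))
  expect_true(all(lab$trials$state == "sitting"))
  expect_false(lab$included)
})

test_that("raising the threshold never converts sitting to running", {
  set.seed(77)
  t <- seq(0, 60, 0.02)
  v <- abs(stats::rnorm(length(t), 1, 2))
  onsets <- 1 + (0:30) * 1.6
  tt <- trial_table(onsets, rep("WN", 31), rep("off", 31))
  tr <- behavior_trace(t, v, 50)
  prev <- label_trials(tt, tr, threshold_fraction = 0.01)$trials$state
  for (f in c(0.05, 0.1, 0.3, 0.6)) {
    cur <- label_trials(tt, tr, threshold_fraction = f)$trials$state
    expect_false(any(prev == "sitting" & cur == "running"))
    prev <- cur
  }
})

test_that("trial windows outside the trace support raise a named error", {
  tt <- trial_table(9.8, "WN", "off")
  tr <- behavior_trace(seq(0, 5, 0.1), rep(0, 51), 10)
  expect_error(label_trials(tt, tr), "trial 1")
})

test_that("arousal gate uses a strict 60%-of-max threshold and reports missing pupil", {
  const <- behavior_trace(seq(0, 1, 0.1), rep(0.8, 11), 10)
  expect_false(any(arousal_gate(const)$mask))

  p <- behavior_trace(c(0, 0.1, 0.2), c(0.5, 0.7, 1.0), 10)
  expect_equal(arousal_gate(p)$mask, c(FALSE, TRUE, TRUE))

  g <- arousal_gate(NULL)
  expect_false(g$available)
  expect_match(g$reason, "pupil")
})

test_that("generated running bouts fall inside the high-arousal pupil mask", {
  g <- generate_session(generator_params(
    n_units = 1, n_trials_per_combo = 30, seed = 5, with_lfp = FALSE))
  s <- g$session
  mask <- arousal_gate(s$pupil)$mask
  running_samples <- s$running$v > 1
  expect_gt(sum(running_samples), 0)
  expect_gt(mean(mask[running_samples]), 0.95)
})
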