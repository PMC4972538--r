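# Generators: determinism, dwell statistics, state-gated spiking, ground
# truth consistency.

test_that("generators are deterministic given a seed", {
  t1 <- simulate_trajectory(duration = 60, seed = 42)
  t2 <- simulate_trajectory(duration = 60, seed = 42)
  expect_identical(t1$traj, t2$traj)
  expect_identical(t1$micro_state, t2$micro_state)

  tr <- simulate_trials(t1, n_trials = 5, seed = 9)
  cells <- make_place_cells(3, seed = 5)
  s1 <- simulate_spikes(cells, t1, tr, seed = 7)
  s2 <- simulate_spikes(cells, t1, tr, seed = 7)
  expect_identical(s1$spikes, s2$spikes)

  e1 <- simulate_emg(tr, seed = 3)
  e2 <- simulate_emg(tr, seed = 3)
  expect_identical(e1$emg$samples, e2$emg$samples)
  expect_identical(e1$blinks, e2$blinks)

  l1 <- simulate_lfp(t1, tr, ripples = s1$ripples, seed = 4)
  l2 <- simulate_lfp(t1, tr, ripples = s1$ripples, seed = 4)
  expect_identical(l1$lfp$samples, l2$lfp$samples)
})

test_that("generator parameter validation", {
  expect_error(simulate_trajectory(duration = -5), "positive")
  expect_error(simulate_trajectory(duration = 10, run_speed = 0), "positive")
  expect_error(simulate_trajectory(duration = 10, sit_mean = -1),
               "non-negative")
  t1 <- simulate_trajectory(duration = 30, seed = 1)
  expect_error(simulate_ripple_events(t1, freq_range = c(60, 200)),
               "\\[80, 250\\]")
  tr <- manual_trials(100)  # beyond the 30 s trajectory
  cells <- make_place_cells(1, seed = 1)
  expect_error(simulate_spikes(cells, t1, tr), "span")
  expect_error(simulate_lfp(t1, n_channels = 2), "3 channels")
  expect_error(simulate_emg(manual_trials(5), cr_prob = 1.2), "\\[0, 1\\]")
})

test_that("zero sit time yields pure traversal at the run speed", {
  t1 <- simulate_trajectory(duration = 60, sit_mean = 0, run_speed = 30,
                            seed = 2)
  expect_true(all(t1$micro_state == "run"))
  sp <- estimate_speed(t1)
  interior <- 10:(length(sp) - 10)
  expect_true(mean(abs(sp[interior] - 30) < 3) > 0.9)
})

test_that("long-run sitting fraction matches the renewal-process stationary law", {
  sit_mean <- 20
  run_speed <- 30
  t1 <- simulate_trajectory(duration = 4000, sit_mean = sit_mean,
                            run_speed = run_speed, seed = 8)
  run_dur <- 180 / run_speed
  expected <- sit_mean / (sit_mean + run_dur)
  observed <- mean(t1$micro_state != "run")
  expect_equal(observed, expected, tolerance = 0.05)
})

test_that("a silent cell produces an empty spike train", {
  t1 <- simulate_trajectory(duration = 60, seed = 3)
  cells <- make_place_cells(1, mix = c(none = 1, endbox = 0, track = 0,
                                       both = 0),
                            baseline_rate = 0, ripple_participation = 0,
                            seed = 1)
  s <- simulate_spikes(cells, t1, quiet_rate = 0, seed = 1)
  expect_length(s$spikes[[1]], 0)
})

test_that("arousal model adds no modulation on run-state trials", {
  t1 <- simulate_trajectory(duration = 300, seed = 4)
  tr <- simulate_trials(t1, n_trials = 20, seed = 4)
  cells <- make_place_cells(4, mix = c(none = 0, endbox = 0, track = 1,
                                       both = 0), seed = 4)
  with_tr <- simulate_spikes(cells, t1, tr, model = "arousal_place_cell",
                             seed = 5, keep_rate = TRUE)
  without <- simulate_spikes(cells, t1, NULL, model = "arousal_place_cell",
                             seed = 5, keep_rate = TRUE)
  # on samples where the animal was already alert, the trial structure leaves
  # the rate trace untouched
  alert <- t1$micro_state %in% c("run", "wander")
  expect_identical(with_tr$rate[, alert], without$rate[, alert])
})

test_that("arousal model: CS during quiet resumes place firing at the field rate", {
  # animal mostly sitting; cell with an endbox field; compare post-CS counts
  # against the configured rate trace over many trials
  t1 <- simulate_trajectory(duration = 2500, sit_mean = 60, seed = 6)
  tr <- simulate_trials(t1, n_trials = 240, iti_range = c(7, 9), seed = 6)
  cells <- make_place_cells(1, mix = c(none = 0, endbox = 1, track = 0,
                                       both = 0), seed = 11)
  s <- simulate_spikes(cells, t1, tr, model = "arousal_place_cell",
                       ripples = data.frame(t = numeric(0),
                                            duration = numeric(0),
                                            freq = numeric(0)),
                       seed = 12, keep_rate = TRUE)
  sit <- tr$micro_state == "pause"
  expect_gt(sum(sit), 150)
  pre <- window_counts(s$spikes[[1]], tr, "pre_cs")
  post <- window_counts(s$spikes[[1]], tr, "post_cs")
  expect_gt(mean(post[sit]), mean(pre[sit]))
  # expected post-CS count from the ground-truth rate trace
  idx <- findInterval(tr$cs_onset[sit], s$rate_times)
  expected_counts <- vapply(which(sit), function(k) {
    w <- s$rate_times >= tr$cs_onset[k] & s$rate_times < tr$cs_onset[k] + 0.5
    sum(s$rate[1, w]) / t1$fs
  }, numeric(1))
  mu <- mean(expected_counts)
  se <- sqrt(mu / sum(sit))   # Poisson error of the mean count
  expect_lt(abs(mean(post[sit]) - mu), 3 * se + 1e-9)
})

test_that("ground-truth ripple count matches the configured quiet-state rate", {
  t1 <- simulate_trajectory(duration = 600, sit_mean = 30, seed = 9)
  ev <- simulate_ripple_events(t1, rate = 0.5, seed = 10)
  quiet_time <- sum(t1$micro_state == "pause") / t1$fs
  expected <- 0.5 * quiet_time
  expect_lt(abs(nrow(ev) - expected), 3 * sqrt(expected))
  ev0 <- simulate_ripple_events(t1, rate = 0, seed = 10)
  expect_equal(nrow(ev0), 0)
})

test_that("LFP ground truth: fixed 8 Hz theta phase advances 2*pi per cycle", {
  t1 <- simulate_trajectory(duration = 30, sit_mean = 0, seed = 12)
  l <- simulate_lfp(t1, theta_freq = 8, theta_freq_sd = 0, seed = 12)
  fs <- l$lfp$fs
  dphi <- wrap_phase(l$theta_phase[1000 + round(fs / 8)] - l$theta_phase[1000])
  expect_lt(abs(dphi), 0.01)
  expect_equal(l$theta_freq[5000], 8)
})

test_that("EMG carries UR bursts on every trial and CRs per the Bernoulli law", {
  tr <- manual_trials(seq(5, 124, by = 4))
  e1 <- simulate_emg(tr, cr_prob = 1, seed = 2)
  expect_true(all(e1$blinks$cr))
  e0 <- simulate_emg(tr, cr_prob = 0, seed = 2)
  expect_false(any(e0$blinks$cr))
  # UR burst raises RMS after the US relative to baseline on every trial
  f <- bandpass(e1$emg, 120, 960)
  ur <- vapply(tr$us_onset, function(u)
    windowed_rms(f, u + 0.02, u + 0.1), numeric(1))
  base <- vapply(tr$cs_onset, function(cs)
    windowed_rms(f, cs - 0.1, cs), numeric(1))
  expect_true(all(ur > 2 * base))
})
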