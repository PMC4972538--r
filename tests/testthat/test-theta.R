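# Theta phase extraction, circular statistics, phase-transition analysis,
# LFP-state classification, phase precession.

test_that("a pure 8 Hz tone yields 8 Hz and accurate phase everywhere", {
  fs <- 1000
  t <- (0:(5 * fs - 1)) / fs
  lfp <- eb_timeseries(cos(2 * pi * 8 * t + 0.9), fs)
  trials <- manual_trials(2.5)
  ens <- extract_theta(lfp, trials, rel_times = seq(-1, 1, by = 0.1))
  expect_true(all(abs(ens$freq - 8) < 0.1))
  truth <- 2 * pi * 8 * (2.5 + seq(-1, 1, by = 0.1)) + 0.9
  err <- wrap_phase(ens$phase[1, ] - truth)
  expect_lt(max(abs(err)), 0.05)
})

test_that("a linear 7 to 9 Hz chirp is tracked within the window resolution", {
  fs <- 1000
  dur <- 20
  t <- (0:(dur * fs - 1)) / fs
  f_inst <- 7 + 2 * t / dur
  phi <- 2 * pi * cumsum(f_inst) / fs
  lfp <- eb_timeseries(cos(phi), fs)
  trials <- manual_trials(10)
  ens <- extract_theta(lfp, trials, rel_times = seq(-5, 5, by = 0.5))
  truth <- 7 + 2 * (10 + seq(-5, 5, by = 0.5)) / dur
  expect_lt(max(abs(ens$freq[1, ] - truth)), 0.3)
})

test_that("a US-like transient cannot reach phase estimates 200 ms away", {
  fs <- 1000
  t <- (0:(6 * fs - 1)) / fs
  base <- cos(2 * pi * 8 * t)
  clean <- eb_timeseries(base, fs)
  dirty_s <- base
  hit <- t >= 3.0 & t < 3.05
  dirty_s[hit] <- dirty_s[hit] + 50 * exp(-(t[hit] - 3) / 0.01)
  dirty <- eb_timeseries(dirty_s, fs)
  trials <- manual_trials(3)
  rel <- c(seq(-1, -0.21, by = 0.05), seq(0.26, 1, by = 0.05))
  e_clean <- extract_theta(clean, trials, rel_times = rel)
  e_dirty <- extract_theta(dirty, trials, rel_times = rel)
  expect_identical(e_clean$phase, e_dirty$phase)
  expect_identical(e_clean$freq, e_dirty$freq)
})

test_that("mean resultant length matches hand arithmetic and theory", {
  expect_equal(mean_resultant(rep(1.2, 10))$R, 1)
  expect_equal(mean_resultant(c(0, pi))$R, 0, tolerance = 1e-12)
  expect_equal(mean_resultant(c(0, pi / 2))$R, sqrt(2) / 2, tolerance = 1e-12)
  # rotation invariance
  set.seed(62)
  ph <- runif(50, -pi, pi)
  expect_equal(mean_resultant(ph)$R, mean_resultant(wrap_phase(ph + 1.1))$R,
               tolerance = 1e-12)
  # E[R] for uniform phases ~ sqrt(pi / (4N))
  N <- 20
  rr <- replicate(2000, mean_resultant(runif(N, -pi, pi))$R)
  expect_equal(mean(rr), sqrt(pi / (4 * N)), tolerance = 0.05)
  expect_true(is.na(mean_resultant(1)$R))
})

test_that("Rayleigh test is calibrated on uniform phases", {
  set.seed(63)
  p <- replicate(2000, mean_resultant(runif(30, -pi, pi))$p)
  expect_lt(mean(p < 0.01), 0.02)
  expect_gt(mean(p < 0.5), 0.3)
  # concentrated phases are detected
  expect_lt(mean_resultant(rnorm(30, 0, 0.3))$p, 1e-6)
})

test_that("phase transition is diagonal across an unbroken theta rhythm", {
  cs <- seq(3, 120, by = 2.7)
  lfp <- make_theta_lfp(cs, mode = "unbroken")
  pt <- phase_transition(lfp, manual_trials(cs), "CS")
  expect_gt(pt$summary$circ_cor, 0.95)
  expect_lt(abs(pt$summary$mean_shift), 0.1)
  expect_gt(pt$summary$shift_R, 0.95)
})

test_that("phase transition identifies a reset to a fixed phase", {
  cs <- seq(3, 200, by = 3.1)
  lfp <- make_theta_lfp(cs, mode = "reset", reset_phase = 1)
  pt <- phase_transition(lfp, manual_trials(cs), "CS")
  expect_gt(pt$summary$post_R, 0.9)
  expect_lt(pt$summary$post_rayleigh_p, 0.01)
  # post phase independent of pre phase: no diagonal structure
  expect_lt(abs(pt$summary$circ_cor), 0.3)
})

test_that("phase transition identifies a constant phase shift", {
  cs <- seq(3, 200, by = 3.1)
  lfp <- make_theta_lfp(cs, mode = "shift", shift = pi / 4)
  pt <- phase_transition(lfp, manual_trials(cs), "CS")
  expect_gt(pt$summary$circ_cor, 0.9)
  expect_lt(abs(wrap_phase(pt$summary$mean_shift - pi / 4)), 0.1)
})

test_that("extrapolation commutes with wrapping over a full period", {
  # advancing a wrapped phase by exactly one period returns the same phase
  f <- 7.7
  phi <- runif(20, -pi, pi)
  adv <- wrap_phase(phi + 2 * pi * f * (1 / f))
  expect_equal(adv, phi, tolerance = 1e-9)
})

test_that("pre-trial LFP state classification follows the power criteria", {
  fs <- 1000
  t <- (0:(40 * fs - 1)) / fs
  theta_seg <- cos(2 * pi * 8 * t)
  delta_seg <- 3 * cos(2 * pi * 2 * t)
  x <- numeric(length(t))
  # trials at 5 (theta), 15 (delta-dominated), 25 (theta), 35 (delta)
  x[t < 10] <- theta_seg[t < 10]
  x[t >= 10 & t < 20] <- delta_seg[t >= 10 & t < 20]
  x[t >= 20 & t < 30] <- theta_seg[t >= 20 & t < 30]
  x[t >= 30] <- delta_seg[t >= 30]
  lfp <- eb_timeseries(x, fs)
  trials <- manual_trials(c(5, 15, 25, 35))
  states <- c("run", "sit", "sit", "sit")
  cls <- classify_trial_lfp_state(lfp, trials, states)
  expect_identical(cls, c("run_theta", "sit_nontheta", "sit_theta",
                          "sit_nontheta"))
})

test_that("phase precession is recovered and stimulus spikes obey the same law", {
  # animal runs repeatedly through a field; spikes precess with the
  # configured negative slope
  fs <- 1000
  v <- 20
  dur <- 360
  t <- (0:(dur * fs - 1)) / fs
  x_pos <- (v * t) %% 180
  f0 <- 7.83          # incommensurate with the traversal period
  lfp <- eb_timeseries(cos(2 * pi * f0 * t), fs)
  slope <- -0.02      # cycles per cm
  set.seed(64)
  # spikes whenever the lfp phase passes the precession target at x
  cand <- seq(1, dur - 1, by = 1 / 40)
  target <- wrap_phase(2 * pi * slope * x_pos[round(cand * fs) + 1] + 2)
  lfp_phase <- wrap_phase(2 * pi * f0 * cand)
  hit <- abs(wrap_phase(lfp_phase - target)) < 0.3 &
    abs(x_pos[round(cand * fs) + 1] - 90) < 25
  spikes <- cand[hit] + runif(sum(hit), 0, 1e-3)
  traj <- manual_trajectory(seq(0, dur - 1 / 25, by = 1 / 25),
                            (v * seq(0, dur - 1 / 25, by = 1 / 25)) %% 180)
  trials <- manual_trials(seq(20, dur - 20, by = 17))
  ov <- phase_precession_overlay(spikes, traj, lfp, trials,
                                 field_range = c(65, 115))
  expect_lt(ov$trend, -0.2)            # negative precession slope recovered
  expect_gt(ov$label_p, 0.01)          # stimulus spikes: same law, no effect
  # no spikes near trials: empty overlay
  ov0 <- phase_precession_overlay(numeric(0), traj, lfp, trials)
  expect_equal(nrow(ov0$spikes), 0)
  expect_true(is.na(ov0$trend))
})
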