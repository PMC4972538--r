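# Rate maps, spatial classification, place-field intensity, pyramidal
# criteria.

test_that("rate is spikes over occupancy by definition", {
  # five traversals at 10 cm/s; one spike while the animal crosses x = 90
  fs <- 25
  leg <- seq(0, 180, by = 10 / fs)
  x <- c(leg, rev(leg), leg, rev(leg), leg)
  t <- (seq_along(x) - 1) / fs
  traj <- manual_trajectory(t, x)
  cross <- t[which(x >= 90)[1]]
  m <- build_rate_map(cross + 1e-4, traj, sigma_track = 0, occ_min = 0)
  bin <- 91  # x in [90, 91)
  occ <- m$track$rightward$occupancy[bin]
  expect_equal(m$track$rightward$raw[bin], 1 / occ)
  # occupancy per bin per direction: 3 rightward passes x (1 cm / 10 cm/s)
  expect_equal(occ, 3 * 0.1, tolerance = 0.2)
})

test_that("a silent cell yields a zero map on valid bins", {
  traj <- simulate_trajectory(duration = 600, seed = 31)
  m <- build_rate_map(numeric(0), traj)
  expect_true(all(m$track$rightward$rate[m$track$rightward$valid] == 0))
  expect_equal(m$spike_count_used, 0L)
})

test_that("homogeneous Poisson firing recovers a flat map at the true rate", {
  traj <- simulate_trajectory(duration = 900, seed = 32)
  r <- 5
  set.seed(32)
  dur <- nrow(traj$traj) / traj$fs
  spikes <- sort(runif(rpois(1, r * dur), 0, dur))
  m <- build_rate_map(spikes, traj)
  v <- m$track$rightward$rate[m$track$rightward$valid]
  expect_equal(mean(v), r, tolerance = 3 * sqrt(r / sum(v >= 0)) / r + 0.05)
})

test_that("Gaussian place fields are recovered with the smoothing broadening", {
  # dense-sampling session: short endbox dwells, so the track is well covered
  traj <- simulate_trajectory(duration = 2400, sit_mean = 5, seed = 33)
  trials <- simulate_trials(traj, n_trials = 100, seed = 33)
  cells <- data.frame(cell = 1, class = "track", track_center = 90,
                      track_sigma = 10, track_dir = "rightward",
                      box_side = NA, box_x = NA, box_y = NA, box_sigma = 4,
                      peak_rate = 8, baseline_rate = 0,
                      ripple_participation = 0)
  spk <- simulate_spikes(cells, traj, trials, quiet_rate = 0, seed = 33)
  m <- build_rate_map(spk$spikes[[1]], traj, trials)
  fit <- fit_track_field(m, "rightward")
  expect_lt(abs(fit["center"] - 90), 1.5)
  expect_lt(abs(fit["peak"] - 8) / 8, 0.2)
  # width broadened by the smoothing kernel: sqrt(sigma_field^2 + sigma_sm^2)
  expect_lt(abs(fit["width"] - sqrt(10^2 + 3^2)) / sqrt(109), 0.2)
  # directionality: the cell never fires leftward
  lt <- m$track$leftward$rate
  expect_lt(max(lt, na.rm = TRUE), 1)
})

test_that("pre-smoothing conservation: every counted spike lands in a bin", {
  traj <- simulate_trajectory(duration = 600, seed = 34)
  trials <- simulate_trials(traj, n_trials = 40, seed = 34)
  cells <- make_place_cells(1, mix = c(none = 0, endbox = 0, track = 0.5,
                                       both = 0.5), seed = 34)
  spk <- simulate_spikes(cells, traj, trials, seed = 34)
  m <- build_rate_map(spk$spikes[[1]], traj, trials)
  binned <- sum(m$track$leftward$count) + sum(m$track$rightward$count) +
    sum(m$box$left$count) + sum(m$box$right$count)
  expect_equal(binned, m$spike_count_used)
  # raw rate x occupancy returns the per-bin spike count
  occ <- m$track$rightward$occupancy
  raw <- m$track$rightward$raw
  nz <- occ > 0 & !is.na(raw)
  expect_equal(raw[nz] * occ[nz], as.numeric(m$track$rightward$count[nz]))
})

test_that("the 2-s post-CS window is excluded from maps", {
  fs <- 25
  leg <- seq(0, 180, by = 10 / fs)
  x <- rep(c(leg, rev(leg)), 3)
  t <- (seq_along(x) - 1) / fs
  traj <- manual_trajectory(t, x)
  trials <- manual_trials(10)
  # a spike 1 s after the CS is inside the exclusion window
  m <- build_rate_map(11, traj, trials, occ_min = 0)
  expect_equal(m$spike_count_used, 0L)
  m2 <- build_rate_map(11, traj, NULL, occ_min = 0)
  expect_equal(m2$spike_count_used, 1L)
})

test_that("spatial classification distinguishes field locations", {
  expect_equal(classify_spatial(manual_ratemap())$class, "no_field")
  m <- manual_ratemap(box_right = 5)
  expect_equal(classify_spatial(m)$class, "endbox_only")
  expect_equal(classify_spatial(m)$peak, 5)
  m2 <- manual_ratemap(track_left = 6, box_right = 5)
  expect_equal(classify_spatial(m2)$class, "track_and_endbox")
  m3 <- manual_ratemap(track_right = 3)
  expect_equal(classify_spatial(m3)$class, "track_only")
  # sub-threshold everywhere stays no_field at a raised threshold
  expect_equal(classify_spatial(m3, peak_thresh = 5)$class, "no_field")
})

test_that("place-field intensity averages the map along the trajectory", {
  env <- eb_env()
  t <- seq(0, 100, by = 0.04)
  # constant map: any window returns the constant
  m <- manual_ratemap(track_left = 3.5, track_right = 3.5, box_left = 3.5,
                      box_right = 3.5)
  traj <- manual_trajectory(t, x = 20 * t %% 180)
  expect_equal(place_field_intensity(m, traj, 10, 12), 3.5)
  # stationary animal: the map value at its location
  still <- manual_trajectory(t, x = rep(120.5, length(t)))
  ramp_rate <- seq(0, 10, length.out = 180)
  mr <- manual_ratemap()
  mr$track$leftward$rate <- ramp_rate
  mr$track$rightward$rate <- ramp_rate
  expect_equal(place_field_intensity(mr, still, 40, 41),
               mean(ramp_rate[120:121]), tolerance = 0.06)
  # full constant-velocity traversal over a linear 0-10 Hz ramp: mean 5 Hz
  leg <- seq(0, 180, length.out = 2501)
  tt <- seq(0, 10, length.out = 2501)
  run <- manual_trajectory(tt, leg)
  expect_equal(place_field_intensity(mr, run, 0, 10), 5, tolerance = 0.05)
  expect_error(place_field_intensity(mr, run, 9, 12), "span")
  expect_error(place_field_intensity(mr, run, 5, 5), "exceed")
})

test_that("pyramidal classification applies the three strict criteria", {
  expect_true(classify_pyramidal(1, 0.3, 0.10))
  expect_false(classify_pyramidal(12, 0.3, 0.10))   # interneuron-like rate
  expect_false(classify_pyramidal(1, 0.2, 0.10))    # narrow spike
  expect_false(classify_pyramidal(1, 0.3, 0.05))    # exactly 5%: strict
  expect_true(is.na(classify_pyramidal(1, NA, 0.10)))
})
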