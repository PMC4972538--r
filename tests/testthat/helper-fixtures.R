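# Fixtures built in code: hand-made trajectories and rate maps used by
# several test files.

# A trajectory object with explicit positions (track coordinates), for tests
# that need exact control over occupancy.
manual_trajectory <- function(t, x, y = rep(0, length(x)), env = eb_env(),
                              micro_state = NULL) {
  fs <- round(1 / stats::median(diff(t)))
  if (is.null(micro_state)) micro_state <- rep("run", length(t))
  structure(list(traj = data.frame(t = t, x = x, y = y,
                                   speed = c(0, sqrt(diff(x)^2 + diff(y)^2)) *
                                     fs),
                 micro_state = micro_state, env = env, fs = fs,
                 params = list()),
            class = "eb_trajectory")
}

# A rate map object with constant or supplied values everywhere, all bins
# valid; geometry matches eb_env().
manual_ratemap <- function(track_left = 0, track_right = 0, box_left = 0,
                           box_right = 0, env = eb_env()) {
  centers <- seq(0.5, env$track_length - 0.5, by = 1)
  mk_t <- function(v) {
    r <- rep(v, length.out = length(centers))
    list(centers = centers, rate = r, raw = r,
         occupancy = rep(1, length(centers)),
         valid = rep(TRUE, length(centers)), count = rep(0, length(centers)))
  }
  mk_b <- function(v, side) {
    xr <- if (side == "left") c(-env$endbox_depth, 0)
          else c(env$track_length, env$track_length + env$endbox_depth)
    xc <- seq(xr[1] + 0.5, xr[2] - 0.5, by = 1)
    yc <- seq(-env$endbox_width / 2 + 0.5, env$endbox_width / 2 - 0.5, by = 1)
    m <- matrix(v, length(xc), length(yc))
    list(x = xc, y = yc, rate = m, raw = m,
         occupancy = matrix(1, length(xc), length(yc)),
         valid = matrix(TRUE, length(xc), length(yc)),
         count = matrix(0, length(xc), length(yc)), bin = 1)
  }
  structure(list(track = list(leftward = mk_t(track_left),
                              rightward = mk_t(track_right)),
                 box = list(left = mk_b(box_left, "left"),
                            right = mk_b(box_right, "right")),
                 env = env, spike_count_used = 0L,
                 params = list(bin_track = 1, bin_box = 1)),
            class = "eb_ratemap")
}

# Gaussian fit to a directional track map: center (cm), peak (Hz), width
# (cm). Independent of the map-construction path.
fit_track_field <- function(map, dir) {
  m <- map$track[[dir]]
  ok <- !is.na(m$rate)
  d <- data.frame(x = m$centers[ok], r = m$rate[ok])
  fit <- stats::nls(r ~ p * exp(-(x - c0)^2 / (2 * w^2)), data = d,
                    start = list(p = max(d$r), c0 = d$x[which.max(d$r)],
                                 w = 10))
  co <- stats::coef(fit)
  c(center = unname(co["c0"]), peak = unname(co["p"]),
    width = abs(unname(co["w"])))
}

# Minimal trial table at given CS onsets.
manual_trials <- function(cs_onset) {
  data.frame(trial = seq_along(cs_onset), cs_onset = cs_onset,
             us_onset = cs_onset + 0.5, cs_duration = 0.25,
             trace_duration = 0.25, us_duration = 0.01)
}
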