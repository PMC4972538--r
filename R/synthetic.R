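# Synthetic-session generator. Implements the arousal-gated place-cell
# account of stimulus-evoked CA1 firing, plus the two alternative response
# models (pure CS cells and conjunctive CS-place cells), so that every
# analysis stage can be verified by parameter recovery on sessions with a
# known ground truth.

# Run an expression under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Environment geometry for a linear-track conditioning session
#'
#' A 180 cm x 7.5 cm linear track terminated by a 22 x 16 cm endbox at each
#' end. Track coordinates run along x from 0 to `track_length` with y = 0 at
#' the track midline; the left endbox occupies x in `[-endbox_depth, 0]` and
#' the right endbox x in `[track_length, track_length + endbox_depth]`.
#'
#' @param track_length,track_width track dimensions in cm
#' @param endbox_depth,endbox_width endbox dimensions in cm (depth along x)
#' @return an `eb_env` list of dimensions
#' @export
eb_env <- function(track_length = 180, track_width = 7.5,
                   endbox_depth = 22, endbox_width = 16) {
  dims <- c(track_length, track_width, endbox_depth, endbox_width)
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("all environment dimensions must be strictly positive")
  structure(list(track_length = track_length, track_width = track_width,
                 endbox_depth = endbox_depth, endbox_width = endbox_width),
            class = "eb_env")
}

# Region of a position: "track", "box_left", "box_right" (or "out").
position_region <- function(env, x, y) {
  r <- rep("out", length(x))
  r[x >= 0 & x <= env$track_length] <- "track"
  r[x < 0 & x >= -env$endbox_depth & abs(y) <= env$endbox_width / 2] <- "box_left"
  r[x > env$track_length & x <= env$track_length + env$endbox_depth &
      abs(y) <= env$endbox_width / 2] <- "box_right"
  r
}

#' Simulate an alternating run/sit trajectory
#'
#' Behaviour alternates between full track traversals at `run_speed` and
#' endbox dwells whose durations are exponential with mean `sit_mean`.
#' Within an endbox dwell the animal alternates stationary pauses
#' (exponential, mean `pause_mean`) with short wanders at `wander_speed` to
#' random points inside the box, returning to the track entrance at the end
#' of the dwell, so that endboxes accrue moving-state occupancy and place
#' maps can be estimated there. `sit_mean = 0` yields uninterrupted
#' traversals. The stationary fraction of time spent in the endboxes is
#' `sit_mean / (sit_mean + track_length/run_speed)`.
#'
#' @param env an [eb_env()]
#' @param duration session length in seconds
#' @param fs position sample rate in Hz (default 25)
#' @param run_speed traversal speed in cm/s
#' @param sit_mean mean endbox dwell in s (0 for none)
#' @param pause_mean mean stationary pause within a dwell in s
#' @param wander_speed within-box movement speed in cm/s
#' @param seed integer RNG seed
#' @return an `eb_trajectory`: data.frame `t, x, y, speed` plus a
#'   `micro_state` factor per sample (`run`, `wander`, `pause`) and the
#'   generating parameters
#' @export
simulate_trajectory <- function(env = eb_env(), duration, fs = 25,
                                run_speed = 30, sit_mean = 20,
                                pause_mean = 4, wander_speed = 5,
                                seed = 1L) {
  if (!is.finite(duration) || duration <= 0) stop("duration must be positive")
  if (run_speed <= 0 || wander_speed <= 0) stop("speeds must be positive")
  if (sit_mean < 0 || pause_mean < 0) stop("dwell parameters must be non-negative")
  with_seed(seed, {
    dt <- 1 / fs
    n <- ceiling(duration * fs)
    # segment plan: each segment is (duration, x0,y0 -> x1,y1, micro state)
    segs <- list()
    add_seg <- function(dur, p0, p1, st) {
      segs[[length(segs) + 1L]] <<- list(dur = dur, p0 = p0, p1 = p1, st = st)
    }
    box_centre <- function(side) {
      x0 <- if (side == "left") -env$endbox_depth / 2 else env$track_length + env$endbox_depth / 2
      c(x0, 0)
    }
    gate <- function(side) c(if (side == "left") 0 else env$track_length, 0)
    rand_box_point <- function(side) {
      xr <- if (side == "left") c(-env$endbox_depth + 2, -2)
            else c(env$track_length + 2, env$track_length + env$endbox_depth - 2)
      c(stats::runif(1, xr[1], xr[2]),
        stats::runif(1, -env$endbox_width / 2 + 2, env$endbox_width / 2 - 2))
    }
    side <- "left"
    pos <- gate(side)
    total <- 0
    while (total < duration) {
      if (sit_mean > 0) {
        dwell <- stats::rexp(1, 1 / sit_mean)
        left <- dwell
        while (left > 0) {
          ret_t <- sqrt(sum((pos - gate(side))^2)) / wander_speed
          if (left <= ret_t + dt) {
            # return to the gate, absorbing exactly the remaining dwell time
            add_seg(max(left, dt), pos, gate(side), "wander")
            pos <- gate(side)
            left <- 0
          } else if (stats::runif(1) < 0.5) {
            p <- min(stats::rexp(1, 1 / max(pause_mean, 1e-6)), left - ret_t)
            if (p > dt) add_seg(p, pos, pos, "pause")
            left <- left - p
          } else {
            tgt <- rand_box_point(side)
            w <- sqrt(sum((tgt - pos)^2)) / wander_speed
            if (w < left - ret_t) {
              add_seg(w, pos, tgt, "wander")
              pos <- tgt
              left <- left - w
            } else {
              p <- min(left - ret_t, stats::rexp(1, 1 / max(pause_mean, 1e-6)))
              if (p > dt) add_seg(p, pos, pos, "pause")
              left <- left - max(p, dt)
            }
          }
        }
        total <- total + dwell
      } else {
        pos <- gate(side)
      }
      # traversal to the other side
      other <- if (side == "left") "right" else "left"
      run_dur <- env$track_length / run_speed
      add_seg(run_dur, gate(side), gate(other), "run")
      pos <- gate(other)
      side <- other
      total <- total + run_dur
    }
    # rasterize segments onto the sample grid
    t_grid <- (seq_len(n) - 1L) * dt
    x <- y <- numeric(n)
    st <- character(n)
    cum <- 0
    i <- 1L
    for (sg in segs) {
      if (i > n) break
      j <- min(n, ceiling((cum + sg$dur) / dt))
      if (j >= i) {
        frac <- if (sg$dur > 0) pmin(1, pmax(0, (t_grid[i:j] - cum) / sg$dur)) else 0
        x[i:j] <- sg$p0[1] + frac * (sg$p1[1] - sg$p0[1])
        y[i:j] <- sg$p0[2] + frac * (sg$p1[2] - sg$p0[2])
        st[i:j] <- sg$st
        i <- j + 1L
      }
      cum <- cum + sg$dur
    }
    if (i <= n) {  # trailing samples, stationary
      x[i:n] <- x[i - 1L]; y[i:n] <- y[i - 1L]; st[i:n] <- "pause"
    }
    vx <- c(0, diff(x)) * fs
    vy <- c(0, diff(y)) * fs
    traj <- data.frame(t = t_grid, x = x, y = y,
                       speed = sqrt(vx^2 + vy^2))
    structure(list(traj = traj, micro_state = st, env = env, fs = fs,
                   params = list(run_speed = run_speed, sit_mean = sit_mean,
                                 pause_mean = pause_mean,
                                 wander_speed = wander_speed, seed = seed)),
              class = "eb_trajectory")
  })
}

#' @export
print.eb_trajectory <- function(x, ...) {
  cat(sprintf("<eb_trajectory> %.0f s at %g Hz; %.0f%% run / %.0f%% wander / %.0f%% pause\n",
              nrow(x$traj) / x$fs, x$fs,
              100 * mean(x$micro_state == "run"),
              100 * mean(x$micro_state == "wander"),
              100 * mean(x$micro_state == "pause")))
  invisible(x)
}

#' Generate an eyeblink trial table
#'
#' Trials follow the conditioning protocol: a 250 ms tone (CS), a 250 ms
#' stimulus-free trace interval, then a 10 ms eyelid stimulation (US), so US
#' onset is 500 ms after CS onset. Inter-trial intervals are uniform on
#' `iti_range`. Delivery location and the generator's micro state at delivery
#' are recorded from the trajectory.
#'
#' @param traj an `eb_trajectory`
#' @param n_trials number of trials (truncated if the session is too short)
#' @param iti_range inter-trial interval range in seconds
#' @param cs_duration,trace_duration,us_duration stimulus timing in seconds
#' @param seed integer RNG seed
#' @return a data.frame with one row per trial: `trial, cs_onset, us_onset,
#'   cs_duration, trace_duration, us_duration, x, y, speed, micro_state`
#' @export
simulate_trials <- function(traj, n_trials = 100, iti_range = c(8, 12),
                            cs_duration = 0.25, trace_duration = 0.25,
                            us_duration = 0.01, seed = 1L) {
  stopifnot(inherits(traj, "eb_trajectory"))
  with_seed(seed, {
    t_max <- max(traj$traj$t) - 3
    onsets <- 5 + cumsum(stats::runif(n_trials, iti_range[1], iti_range[2]))
    onsets <- onsets[onsets < t_max]
    idx <- findInterval(onsets, traj$traj$t)
    data.frame(trial = seq_along(onsets),
               cs_onset = onsets,
               us_onset = onsets + cs_duration + trace_duration,
               cs_duration = cs_duration,
               trace_duration = trace_duration,
               us_duration = us_duration,
               x = traj$traj$x[idx], y = traj$traj$y[idx],
               speed = traj$traj$speed[idx],
               micro_state = traj$micro_state[idx],
               stringsAsFactors = FALSE)
  })
}

#' Ground-truth place-cell population
#'
#' Draws a population with the spatial-class mix observed in dorsal CA1 on
#' this apparatus: cells with no field, a field in one endbox only, a
#' directional field on the track only, or both. Track fields are Gaussian
#' tuning curves active in one running direction; endbox fields are 2-D
#' Gaussians, non-directional.
#'
#' @param n number of cells
#' @param env an [eb_env()]
#' @param mix probabilities for classes `none`, `endbox`, `track`, `both`
#' @param peak_rate field peak in Hz
#' @param sigma_track track field width (Gaussian sigma) in cm
#' @param sigma_box endbox field sigma in cm
#' @param baseline_rate out-of-field alert-state rate in Hz
#' @param ripple_participation probability a cell bursts in a given ripple
#' @param seed integer RNG seed
#' @return data.frame of per-cell ground truth (one row per cell)
#' @export
make_place_cells <- function(n, env = eb_env(),
                             mix = c(none = 0.38, endbox = 0.24,
                                     track = 0.26, both = 0.12),
                             peak_rate = 8, sigma_track = 10, sigma_box = 4,
                             baseline_rate = 0.1,
                             ripple_participation = 0.3, seed = 1L) {
  stopifnot(abs(sum(mix) - 1) < 1e-9, peak_rate >= baseline_rate,
            baseline_rate >= 0, sigma_track > 0, sigma_box > 0,
            ripple_participation >= 0, ripple_participation <= 1)
  with_seed(seed, {
    cls <- sample(names(mix), n, replace = TRUE, prob = mix)
    has_track <- cls %in% c("track", "both")
    has_box <- cls %in% c("endbox", "both")
    side <- sample(c("left", "right"), n, replace = TRUE)
    bx0 <- ifelse(side == "left", -env$endbox_depth / 2,
                  env$track_length + env$endbox_depth / 2)
    data.frame(cell = seq_len(n), class = cls,
               track_center = ifelse(has_track,
                                     stats::runif(n, 10, env$track_length - 10), NA),
               track_sigma = sigma_track,
               track_dir = ifelse(has_track,
                                  sample(c("leftward", "rightward"), n, replace = TRUE),
                                  NA),
               box_side = ifelse(has_box, side, NA),
               box_x = ifelse(has_box, bx0 + stats::runif(n, -6, 6), NA),
               box_y = ifelse(has_box, stats::runif(n, -4, 4), NA),
               box_sigma = sigma_box,
               peak_rate = peak_rate,
               baseline_rate = baseline_rate,
               ripple_participation = ripple_participation,
               stringsAsFactors = FALSE)
  })
}

# Place-driven rate for one cell at positions (x, y) with movement direction
# dir ("leftward"/"rightward"/NA for stationary). Stationary-on-track alert
# samples take the mean over the two directional maps.
cell_place_rate <- function(cell, env, x, y, dir) {
  r <- rep(0, length(x))
  region <- position_region(env, x, y)
  on_track <- region == "track"
  if (!is.na(cell$track_center)) {
    g <- cell$peak_rate * exp(-(x - cell$track_center)^2 / (2 * cell$track_sigma^2))
    match_dir <- on_track & !is.na(dir) & dir == cell$track_dir
    stat_track <- on_track & is.na(dir)
    r[match_dir] <- g[match_dir]
    r[stat_track] <- g[stat_track] / 2   # mean of the two directional maps
  }
  if (!is.na(cell$box_x)) {
    in_box <- region == paste0("box_", cell$box_side)
    g <- cell$peak_rate *
      exp(-((x - cell$box_x)^2 + (y - cell$box_y)^2) / (2 * cell$box_sigma^2))
    r[in_box] <- pmax(r[in_box], g[in_box])
  }
  r
}

# Alert mask per trajectory sample: moving states are always alert; under the
# arousal model, quiet samples inside a post-CS arousal window are alert too.
alert_mask <- function(traj, trials = NULL, model = "arousal_place_cell",
                       arousal_latency = 0.05, alert_duration = 2.5) {
  alert <- traj$micro_state %in% c("run", "wander")
  win <- NULL
  if (!is.null(trials) && model == "arousal_place_cell" && nrow(trials)) {
    idx <- findInterval(trials$cs_onset, traj$traj$t)
    quiet_at_cs <- traj$micro_state[idx] == "pause"
    if (any(quiet_at_cs)) {
      win <- data.frame(t_start = trials$cs_onset[quiet_at_cs] + arousal_latency,
                        t_end = trials$cs_onset[quiet_at_cs] + arousal_latency +
                          alert_duration)
      for (k in seq_len(nrow(win)))
        alert <- alert | (traj$traj$t >= win$t_start[k] & traj$traj$t < win$t_end[k])
    }
  }
  list(alert = alert, windows = win)
}

#' Ground-truth ripple event times
#'
#' Ripples occur as a Poisson process confined to quiet (paused, non-aroused)
#' samples. Under the arousal model the post-CS arousal windows are excluded,
#' so ripples cease after the CS on sitting trials.
#'
#' @param traj an `eb_trajectory`
#' @param trials trial table (may be `NULL`)
#' @param rate ripple rate during quiet wakefulness, events/s
#' @param model response model (see [simulate_spikes()])
#' @param freq_range ripple centre-frequency range in Hz
#' @param duration_range event duration range in s
#' @param arousal_latency,alert_duration arousal-model timing in s
#' @param seed integer RNG seed
#' @return data.frame `t` (peak time), `duration`, `freq`
#' @export
simulate_ripple_events <- function(traj, trials = NULL, rate = 0.4,
                                   model = "arousal_place_cell",
                                   freq_range = c(140, 200),
                                   duration_range = c(0.03, 0.1),
                                   arousal_latency = 0.05,
                                   alert_duration = 2.5, seed = 1L) {
  stopifnot(rate >= 0)
  if (freq_range[1] < 80 || freq_range[2] > 250)
    stop("ripple centre frequency must lie within [80, 250] Hz")
  with_seed(seed, {
    am <- alert_mask(traj, trials, model, arousal_latency, alert_duration)
    quiet <- !am$alert
    dt <- 1 / traj$fs
    p <- rate * dt
    hit <- which(quiet & stats::runif(nrow(traj$traj)) < p)
    if (!length(hit))
      return(data.frame(t = numeric(0), duration = numeric(0), freq = numeric(0)))
    t <- traj$traj$t[hit] + stats::runif(length(hit), 0, dt)
    data.frame(t = t,
               duration = stats::runif(length(hit), duration_range[1], duration_range[2]),
               freq = stats::runif(length(hit), freq_range[1], freq_range[2]))
  })
}

#' Simulate spike trains under a response model
#'
#' Inhomogeneous-Poisson spiking given the model's rate trace. During alert
#' epochs (moving, or post-CS arousal under the arousal model) a cell fires
#' at its place-field rate at the current position and running direction plus
#' its baseline. During quiet epochs place-specific firing is suppressed to
#' `quiet_rate` and cells instead emit ripple-associated bursts: in each
#' ripple a cell participates with its `ripple_participation` probability,
#' adding `Poisson(burst_mean)` spikes within the ripple window.
#'
#' Models: `"arousal_place_cell"` — the CS switches quiet to alert after
#' `arousal_latency`, with no other added modulation; `"cs_cell"` — cells
#' fire homogeneously at their baseline and the CS adds a space-invariant
#' rate bump `cs_gain` for `cs_response_dur` (no state gating, no place
#' fields); `"cs_place_cell"` — place/state background without arousal
#' switching, and the CS adds a bump `cs_gain *` (field rate at the current
#' location) regardless of state.
#'
#' @param cells data.frame from [make_place_cells()]
#' @param traj an `eb_trajectory`
#' @param trials trial table from [simulate_trials()] (or `NULL`)
#' @param model one of `"arousal_place_cell"`, `"cs_cell"`, `"cs_place_cell"`
#' @param ripples ground-truth ripple events ([simulate_ripple_events()]);
#'   generated internally when `NULL` and the session has quiet epochs
#' @param cs_gain CS response gain: Hz for `cs_cell`, dimensionless for
#'   `cs_place_cell`
#' @param cs_latency CS response latency in s
#' @param cs_response_dur CS response duration in s
#' @param arousal_latency,alert_duration arousal-model timing in s
#' @param quiet_rate residual inter-ripple quiet-state rate in Hz
#' @param burst_mean mean spikes per participated ripple
#' @param seed integer RNG seed
#' @param keep_rate keep the per-cell rate traces (cells x samples matrix)
#' @return `eb_spikes`: list with `spikes` (list of sorted spike-time
#'   vectors), `cells`, `ripples`, model parameters, optional `rate`
#' @export
simulate_spikes <- function(cells, traj, trials = NULL,
                            model = c("arousal_place_cell", "cs_cell",
                                      "cs_place_cell"),
                            ripples = NULL, cs_gain = 3, cs_latency = 0.05,
                            cs_response_dur = 0.5, arousal_latency = 0.05,
                            alert_duration = 2.5, quiet_rate = 0.02,
                            burst_mean = 2, seed = 1L, keep_rate = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(traj, "eb_trajectory"))
  tt <- traj$traj$t
  if (!is.null(trials) && nrow(trials) &&
      (min(trials$cs_onset) < min(tt) || max(trials$us_onset) + 1 > max(tt)))
    stop("trials fall outside the trajectory time span")
  with_seed(seed, {
    n <- nrow(traj$traj)
    dt <- 1 / traj$fs
    env <- traj$env
    dir <- rep(NA_character_, n)
    moving <- traj$micro_state %in% c("run", "wander")
    vx <- c(0, diff(traj$traj$x)) * traj$fs
    dir[moving & vx > 0] <- "rightward"
    dir[moving & vx < 0] <- "leftward"
    am <- alert_mask(traj, trials, model, arousal_latency, alert_duration)
    if (is.null(ripples) && model != "cs_cell") {
      ripples <- simulate_ripple_events(traj, trials, model = model,
                                        arousal_latency = arousal_latency,
                                        alert_duration = alert_duration,
                                        seed = seed + 7777L)
    }
    # space-invariant CS bump indicator on the sample grid
    bump <- rep(0, n)
    if (!is.null(trials) && nrow(trials) && model != "arousal_place_cell") {
      for (k in seq_len(nrow(trials))) {
        w <- tt >= trials$cs_onset[k] + cs_latency &
          tt < trials$cs_onset[k] + cs_latency + cs_response_dur
        bump[w] <- 1
      }
    }
    rate_mat <- if (keep_rate) matrix(0, nrow(cells), n) else NULL
    spikes <- vector("list", nrow(cells))
    for (ci in seq_len(nrow(cells))) {
      cell <- cells[ci, ]
      if (model == "cs_cell") {
        r <- cell$baseline_rate + cs_gain * bump
      } else {
        place <- cell_place_rate(cell, env, traj$traj$x, traj$traj$y, dir)
        r <- ifelse(am$alert, cell$baseline_rate + place, quiet_rate)
        if (model == "cs_place_cell")
          r <- r + cs_gain * bump *
            cell_place_rate(cell, env, traj$traj$x, traj$traj$y,
                            ifelse(is.na(dir), NA, dir))
      }
      if (keep_rate) rate_mat[ci, ] <- r
      counts <- stats::rpois(n, r * dt)
      hit <- which(counts > 0)
      st <- rep(tt[hit], counts[hit]) + stats::runif(sum(counts), 0, dt)
      # ripple-associated bursts while quiet
      if (!is.null(ripples) && nrow(ripples) && model != "cs_cell") {
        part <- which(stats::runif(nrow(ripples)) < cell$ripple_participation)
        if (length(part)) {
          nb <- stats::rpois(length(part), burst_mean)
          bt <- rep(ripples$t[part], nb) +
            stats::runif(sum(nb), 0, rep(ripples$duration[part], nb)) -
            rep(ripples$duration[part], nb) / 2
          st <- c(st, bt)
        }
      }
      spikes[[ci]] <- sort(st)
    }
    structure(list(spikes = spikes, cells = cells, ripples = ripples,
                   model = model,
                   params = list(cs_gain = cs_gain, cs_latency = cs_latency,
                                 cs_response_dur = cs_response_dur,
                                 arousal_latency = arousal_latency,
                                 alert_duration = alert_duration,
                                 quiet_rate = quiet_rate,
                                 burst_mean = burst_mean, seed = seed),
                   arousal_windows = am$windows,
                   rate = rate_mat, rate_times = if (keep_rate) tt else NULL),
              class = "eb_spikes")
  })
}

#' @export
print.eb_spikes <- function(x, ...) {
  cat(sprintf("<eb_spikes> %d cell(s), model '%s', %d spikes total\n",
              length(x$spikes), x$model, sum(lengths(x$spikes))))
  invisible(x)
}

#' Simulate a multi-channel hippocampal LFP
#'
#' Additive synthesis: pink background noise on every channel (larger during
#' quiet epochs, emulating large irregular activity), a theta oscillation
#' during alert epochs whose frequency drifts around `theta_freq` (an
#' Ornstein-Uhlenbeck excursion), and Gaussian-windowed ripple wavelets at
#' the ground-truth event times, synchronized across `ripple_channels`.
#' Optionally a high-amplitude decaying transient after each US.
#'
#' @param traj an `eb_trajectory`
#' @param trials trial table or `NULL`
#' @param ripples ground-truth ripple events
#' @param n_channels number of channels (>= 3)
#' @param fs LFP sample rate in Hz
#' @param theta_freq,theta_freq_sd theta centre frequency and drift SD (Hz)
#' @param theta_amp theta amplitude (uV)
#' @param noise_amp background noise SD (uV)
#' @param ripple_amp ripple wavelet amplitude (uV)
#' @param ripple_channels channel indices carrying ripples (default all)
#' @param us_artifact add a post-US transient
#' @param model response model (controls arousal gating of theta/ripples)
#' @param arousal_latency,alert_duration arousal-model timing in s
#' @param seed integer RNG seed
#' @return `eb_lfp`: an [eb_timeseries()] matrix plus ground truth
#'   (`theta_phase`, `theta_freq` vectors at the LFP rate, `ripples`)
#' @export
simulate_lfp <- function(traj, trials = NULL, ripples = NULL, n_channels = 4,
                         fs = 1000, theta_freq = 8, theta_freq_sd = 0.5,
                         theta_amp = 100, noise_amp = 30, ripple_amp = 60,
                         ripple_channels = NULL, us_artifact = FALSE,
                         model = "arousal_place_cell", arousal_latency = 0.05,
                         alert_duration = 2.5, seed = 1L) {
  if (n_channels < 3) stop("at least 3 channels are required for ripple detection")
  if (!is.null(ripples) && nrow(ripples) &&
      (min(ripples$freq) < 80 || max(ripples$freq) > 250))
    stop("ripple centre frequency must lie within [80, 250] Hz")
  with_seed(seed, {
    dur <- nrow(traj$traj) / traj$fs
    n <- floor(dur * fs)
    t <- (seq_len(n) - 1L) / fs
    am <- alert_mask(traj, trials, model, arousal_latency, alert_duration)
    alert_hi <- am$alert[pmin(nrow(traj$traj), floor(t * traj$fs) + 1L)]
    # theta instantaneous frequency: OU around theta_freq (tau = 2 s)
    phi_ou <- exp(-1 / (2 * fs))
    drift <- stats::filter(stats::rnorm(n, 0, theta_freq_sd * sqrt(1 - phi_ou^2)),
                           phi_ou, method = "recursive")
    f_inst <- theta_freq + as.numeric(drift)
    theta_phase <- wrap_phase(2 * pi * cumsum(f_inst) / fs)
    theta <- theta_amp * cos(theta_phase) * alert_hi
    if (is.null(ripple_channels)) ripple_channels <- seq_len(n_channels)
    quiet_gain <- ifelse(alert_hi, 1, 1.5)
    mk_noise <- function() {
      w <- stats::rnorm(n)
      p <- as.numeric(stats::filter(w, 0.98, method = "recursive"))
      p <- p / stats::sd(p)
      (0.7 * p + 0.5 * w) * noise_amp * quiet_gain
    }
    smp <- matrix(0, n, n_channels)
    for (ch in seq_len(n_channels)) smp[, ch] <- mk_noise() + theta
    if (!is.null(ripples) && nrow(ripples)) {
      for (k in seq_len(nrow(ripples))) {
        i0 <- round(ripples$t[k] * fs)
        hw <- round(ripples$duration[k] * fs / 2)
        idx <- (i0 - hw):(i0 + hw)
        idx <- idx[idx >= 1 & idx <= n]
        if (!length(idx)) next
        tau <- (idx - 1) / fs - ripples$t[k]
        wav <- ripple_amp * exp(-tau^2 / (2 * (ripples$duration[k] / 4)^2)) *
          cos(2 * pi * ripples$freq[k] * tau)
        for (ch in ripple_channels)
          smp[idx, ch] <- smp[idx, ch] + wav * stats::runif(1, 0.8, 1.2)
      }
    }
    if (us_artifact && !is.null(trials) && nrow(trials)) {
      for (k in seq_len(nrow(trials))) {
        i0 <- round(trials$us_onset[k] * fs)
        idx <- i0:min(n, i0 + round(0.05 * fs))
        idx <- idx[idx >= 1]
        smp[idx, ] <- smp[idx, ] +
          10 * theta_amp * exp(-((idx - i0) / fs) / 0.01)
      }
    }
    structure(list(lfp = eb_timeseries(smp, fs),
                   theta_phase = theta_phase, theta_freq = f_inst,
                   alert = alert_hi, ripples = ripples,
                   params = list(theta_freq = theta_freq,
                                 theta_freq_sd = theta_freq_sd,
                                 theta_amp = theta_amp, noise_amp = noise_amp,
                                 ripple_amp = ripple_amp, seed = seed)),
              class = "eb_lfp")
  })
}

#' @export
print.eb_lfp <- function(x, ...) {
  cat(sprintf("<eb_lfp> %d channel(s), %.0f s at %g Hz, %d ground-truth ripple(s)\n",
              ts_nchan(x$lfp), ts_duration(x$lfp), x$lfp$fs,
              if (is.null(x$ripples)) 0L else nrow(x$ripples)))
  invisible(x)
}

#' Simulate a differential eyelid EMG trace
#'
#' Broadband Gaussian baseline noise with an unconditioned blink burst after
#' the US on every trial and a conditioned-response burst in the 380-480 ms
#' pre-US window on Bernoulli(`cr_prob`) trials. Bursts are amplitude-scaled
#' white noise shaped by a Hann envelope, so their spectrum spans the
#' 120-960 Hz detection band.
#'
#' @param trials trial table
#' @param duration trace length in s (defaults to cover all trials)
#' @param cr_prob per-trial conditioned-response probability, scalar or
#'   vector of length `nrow(trials)`
#' @param fs sample rate in Hz
#' @param noise_sd baseline noise SD
#' @param cr_amp,ur_amp burst amplitudes (multiples of `noise_sd`)
#' @param seed integer RNG seed
#' @return `eb_emg`: an [eb_timeseries()] plus ground-truth blink log
#'   (data.frame `trial, cr`)
#' @export
simulate_emg <- function(trials, duration = NULL, cr_prob = 0.7, fs = 2000,
                         noise_sd = 1, cr_amp = 6, ur_amp = 8, seed = 1L) {
  if (any(cr_prob < 0 | cr_prob > 1)) stop("cr_prob must lie in [0, 1]")
  cr_prob <- rep(cr_prob, length.out = nrow(trials))
  if (is.null(duration)) duration <- max(trials$us_onset) + 2
  with_seed(seed, {
    n <- floor(duration * fs)
    x <- stats::rnorm(n, 0, noise_sd)
    add_burst <- function(x, t0, t1, amp) {
      i <- max(1L, round(t0 * fs)):min(n, round(t1 * fs))
      env <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = length(i)))
      x[i] <- x[i] + amp * noise_sd * env * stats::rnorm(length(i))
      x
    }
    cr <- stats::runif(nrow(trials)) < cr_prob
    for (k in seq_len(nrow(trials))) {
      cs <- trials$cs_onset[k]
      if (cr[k]) x <- add_burst(x, cs + 0.38, cs + 0.48, cr_amp)
      x <- add_burst(x, trials$us_onset[k] + trials$us_duration[k],
                     trials$us_onset[k] + trials$us_duration[k] + 0.1, ur_amp)
    }
    structure(list(emg = eb_timeseries(x, fs),
                   blinks = data.frame(trial = trials$trial, cr = cr),
                   params = list(cr_prob = cr_prob, noise_sd = noise_sd,
                                 cr_amp = cr_amp, ur_amp = ur_amp, seed = seed)),
              class = "eb_emg")
  })
}

#' Simulate a complete conditioning session
#'
#' Convenience wrapper generating a trajectory, trial table, place-cell
#' population, ground-truth ripples, spike trains, LFP and EMG under one
#' response model, with sub-seeds derived from `seed` so the whole session is
#' reproducible from a single integer.
#'
#' @param n_cells number of units
#' @param n_trials number of eyeblink trials
#' @param duration session length in s (default sized from `n_trials`)
#' @param model response model, see [simulate_spikes()]
#' @param include_lfp,include_emg generate the LFP / EMG components
#' @param seed integer RNG seed
#' @param ... passed to [simulate_spikes()]
#' @return `eb_session`: list with `traj`, `trials`, `cells`, `spk`
#'   (`eb_spikes`), `lfp` (`eb_lfp` or `NULL`), `emg` (`eb_emg` or `NULL`),
#'   `model`, `seed`
#' @export
simulate_session <- function(n_cells = 30, n_trials = 100, duration = NULL,
                             model = "arousal_place_cell",
                             include_lfp = TRUE, include_emg = TRUE,
                             seed = 1L, ...) {
  if (is.null(duration)) duration <- 10 * n_trials + 60
  traj <- simulate_trajectory(duration = duration, seed = seed)
  trials <- simulate_trials(traj, n_trials = n_trials, seed = seed + 1L)
  cells <- make_place_cells(n_cells, traj$env, seed = seed + 2L)
  ripples <- if (model == "cs_cell") NULL else
    simulate_ripple_events(traj, trials, model = model, seed = seed + 3L)
  spk <- simulate_spikes(cells, traj, trials, model = model, ripples = ripples,
                         seed = seed + 4L, ...)
  lfp <- if (include_lfp)
    simulate_lfp(traj, trials, ripples = spk$ripples, model = model,
                 seed = seed + 5L) else NULL
  emg <- if (include_emg) simulate_emg(trials, seed = seed + 6L) else NULL
  structure(list(traj = traj, trials = trials, cells = cells, spk = spk,
                 lfp = lfp, emg = emg, model = model, seed = seed),
            class = "eb_session")
}

#' @export
print.eb_session <- function(x, ...) {
  cat(sprintf("<eb_session> model '%s': %d cells, %d trials, %.0f s (seed %d)\n",
              x$model, nrow(x$cells), nrow(x$trials),
              nrow(x$traj$traj) / x$traj$fs, x$seed))
  invisible(x)
}
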