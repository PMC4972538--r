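# Behavioural analysis: conditioned-response detection from the eyelid EMG
# and locomotor-state classification of trials.

#' Estimate speed from a trajectory
#'
#' Central difference on position smoothed with a boxcar (default 200 ms).
#' Used by [moving_mask()] and [classify_trial_state()].
#'
#' @param traj an `eb_trajectory` or a data.frame with `t, x, y`
#' @param smooth_window boxcar width in seconds
#' @return numeric speed per sample, cm/s
#' @export
estimate_speed <- function(traj, smooth_window = 0.2) {
  df <- if (inherits(traj, "eb_trajectory")) traj$traj else traj
  fs <- 1 / stats::median(diff(df$t))
  k <- max(1L, round(smooth_window * fs))
  k <- k + (1L - k %% 2L)
  box <- rep(1 / k, k)
  sm <- function(v) {
    p <- (k - 1L) %/% 2L
    vp <- c(rep(v[1L], p), v, rep(v[length(v)], p))
    as.numeric(stats::filter(vp, box, sides = 2L))[p + seq_along(v)]
  }
  xs <- sm(df$x); ys <- sm(df$y)
  n <- length(xs)
  vx <- (xs[c(2:n, n)] - xs[c(1, 1:(n - 1))]) /
    (df$t[c(2:n, n)] - df$t[c(1, 1:(n - 1))])
  vy <- (ys[c(2:n, n)] - ys[c(1, 1:(n - 1))]) /
    (df$t[c(2:n, n)] - df$t[c(1, 1:(n - 1))])
  sqrt(vx^2 + vy^2)
}

#' Mask of samples where the animal is moving
#'
#' Place-field construction only uses samples with speed above `v_thresh`
#' (default 2 cm/s).
#'
#' @param traj an `eb_trajectory` or data.frame with `t, x, y`
#' @param v_thresh speed threshold in cm/s
#' @param smooth_window smoothing window for [estimate_speed()], seconds
#' @return logical vector per trajectory sample
#' @export
moving_mask <- function(traj, v_thresh = 2, smooth_window = 0.2) {
  estimate_speed(traj, smooth_window) > v_thresh
}

#' Detect conditioned responses on the eyelid EMG
#'
#' The EMG is band-passed to 120-960 Hz and its RMS computed in three 100 ms
#' windows per trial: baseline (-100 to 0 ms relative to CS onset), CR (380
#' to 480 ms; the US arrives at 500 ms) and control (-580 to -480 ms). A
#' trial is a blink when `CR - baseline` exceeds the session's 95th
#' percentile of `control - baseline` (valid trials only).
#'
#' @param emg a single-channel [eb_timeseries()] (or an `eb_emg`)
#' @param trials trial table with `cs_onset`
#' @param band EMG pass band in Hz
#' @param percentile blink threshold quantile of `control - baseline`
#' @return `eb_cr_result`: per-trial data.frame (`trial, baseline_rms,
#'   cr_rms, control_rms, is_blink, valid`), the session CR rate and its 95%
#'   Bernoulli (normal-approximation) confidence interval, and the threshold
#' @export
detect_crs <- function(emg, trials, band = c(120, 960), percentile = 0.95) {
  if (inherits(emg, "eb_emg")) emg <- emg$emg
  stopifnot(inherits(emg, "eb_timeseries"))
  if (nrow(trials) < 20)
    warning("fewer than 20 trials; the percentile threshold will be unstable")
  f <- bandpass(emg, band[1], band[2])
  t_lo <- f$t0
  t_hi <- f$t0 + ts_duration(f)
  win <- function(cs, a, b) {
    if (cs + a < t_lo || cs + b > t_hi) return(NA_real_)
    windowed_rms(f, cs + a, cs + b)
  }
  base <- ctrl <- crr <- numeric(nrow(trials))
  for (k in seq_len(nrow(trials))) {
    cs <- trials$cs_onset[k]
    base[k] <- win(cs, -0.1, 0)
    crr[k] <- win(cs, 0.38, 0.48)
    ctrl[k] <- win(cs, -0.58, -0.48)
  }
  valid <- is.finite(base) & is.finite(crr) & is.finite(ctrl)
  thr <- stats::quantile(ctrl[valid] - base[valid], percentile, names = FALSE)
  blink <- (crr - base) > thr & valid
  rate <- mean(blink[valid])
  n_valid <- sum(valid)
  se <- sqrt(rate * (1 - rate) / max(n_valid, 1))
  structure(list(trials = data.frame(trial = trials$trial,
                                     baseline_rms = base, cr_rms = crr,
                                     control_rms = ctrl,
                                     is_blink = blink, valid = valid),
                 cr_rate = rate,
                 cr_rate_ci = pmin(1, pmax(0, rate + c(-1.96, 1.96) * se)),
                 threshold = thr, n_valid = n_valid),
            class = "eb_cr_result")
}

#' @export
print.eb_cr_result <- function(x, ...) {
  cat(sprintf("<eb_cr_result> CR rate %.2f [%.2f, %.2f] over %d valid trial(s)\n",
              x$cr_rate, x$cr_rate_ci[1], x$cr_rate_ci[2], x$n_valid))
  invisible(x)
}

#' Classify trials as run / sit / ambiguous
#'
#' The speed is averaged over a pre-CS window (default 500 ms); trials at or
#' above `run_thresh` are `run`, at or below `sit_thresh` are `sit`, and the
#' rest are `ambiguous` (excluded from state-split analyses).
#'
#' @param traj an `eb_trajectory` or data.frame with `t, x, y`
#' @param trials trial table with `cs_onset`
#' @param run_thresh,sit_thresh thresholds in cm/s (`sit_thresh <= run_thresh`)
#' @param pre_window length of the pre-CS averaging window in seconds
#' @return character vector per trial: `run`, `sit`, `ambiguous`, or
#'   `invalid` for trials outside the trajectory span
#' @export
classify_trial_state <- function(traj, trials, run_thresh = 8, sit_thresh = 2,
                                 pre_window = 0.5) {
  if (sit_thresh > run_thresh) stop("sit_thresh must not exceed run_thresh")
  df <- if (inherits(traj, "eb_trajectory")) traj$traj else traj
  sp <- estimate_speed(traj)
  out <- character(nrow(trials))
  for (k in seq_len(nrow(trials))) {
    cs <- trials$cs_onset[k]
    sel <- df$t >= cs - pre_window & df$t < cs
    if (!any(sel) || cs - pre_window < min(df$t) || cs > max(df$t)) {
      out[k] <- "invalid"
      next
    }
    v <- mean(sp[sel])
    out[k] <- if (v >= run_thresh) "run" else if (v <= sit_thresh) "sit" else "ambiguous"
  }
  out
}
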