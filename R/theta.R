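# Theta-phase analysis: instantaneous frequency/phase via the
# locality-guaranteed STFT, circular statistics (mean resultant length,
# Rayleigh test), the phase-transition (reset vs shift) analysis, pre-trial
# LFP-state classification, and the phase-precession overlay.

#' Per-trial instantaneous theta phase, frequency and amplitude
#'
#' For every requested time point relative to each trial's CS onset, the
#' instantaneous theta frequency is the peak of the spectral power density
#' in 4-12 Hz from a 400 ms Kaiser (alpha = 1) STFT frame centred there; the
#' phase and amplitude are the argument and modulus of the STFT coefficient
#' at that frequency. Estimates therefore depend on data within +/- 200 ms
#' only; frames extending past the data are marked invalid.
#'
#' @param lfp a single-channel [eb_timeseries()] (pick a channel with
#'   [ts_channel()])
#' @param trials trial table
#' @param rel_times time points relative to CS onset in s
#' @param band theta band in Hz
#' @param window_length STFT window in s
#' @return `eb_phase_ensemble`: matrices `phase`, `freq`, `amp` (trials x
#'   time points), `rel_times`, trial count `n`
#' @export
extract_theta <- function(lfp, trials, rel_times = seq(-1, 1.5, by = 0.01),
                          band = c(4, 12), window_length = 0.4) {
  stopifnot(inherits(lfp, "eb_timeseries"))
  n <- nrow(trials)
  phase <- freq <- amp <- matrix(NA_real_, n, length(rel_times))
  for (k in seq_len(n)) {
    tk <- trials$cs_onset[k] + rel_times
    s <- stft(lfp, window_length = window_length, times = tk)
    pk <- stft_peak(s, band[1], band[2])
    phase[k, ] <- pk$phase
    freq[k, ] <- pk$freq
    amp[k, ] <- pk$amp
  }
  structure(list(phase = phase, freq = freq, amp = amp,
                 rel_times = rel_times, n = n, band = band,
                 window_length = window_length),
            class = "eb_phase_ensemble")
}

#' @export
print.eb_phase_ensemble <- function(x, ...) {
  cat(sprintf("<eb_phase_ensemble> %d trial(s) x %d time point(s), %g-%g Hz\n",
              x$n, length(x$rel_times), x$band[1], x$band[2]))
  invisible(x)
}

#' Mean resultant length and Rayleigh test
#'
#' `R = |mean(exp(i*phi))|` of a sample of phases: 0 for symmetrically
#' dispersed phases, 1 for perfect alignment. The Rayleigh test p-value for
#' non-uniformity uses the standard finite-sample approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - Rn^2)) - (1 + 2n))` with `Rn = n R`.
#'
#' @param phases numeric vector of phases in radians (`NA` dropped)
#' @param amp optional non-negative weights (amplitude-weighted variant)
#' @return list with `R`, `p`, `n`, `mean_phase`
#' @export
mean_resultant <- function(phases, amp = NULL) {
  ok <- is.finite(phases)
  phases <- phases[ok]
  n <- length(phases)
  if (n < 2L) return(list(R = NA_real_, p = NA_real_, n = n,
                          mean_phase = NA_real_))
  z <- if (is.null(amp)) mean(exp(1i * phases))
       else sum(amp[ok] * exp(1i * phases)) / sum(amp[ok])
  R <- Mod(z)
  Rn <- n * R
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Rn^2)) - (1 + 2 * n))
  list(R = R, p = min(1, p), n = n, mean_phase = Arg(z))
}

#' Cross-trial phase alignment over time
#'
#' Applies [mean_resultant()] at every time point of a phase ensemble.
#'
#' @param ens an `eb_phase_ensemble`
#' @param weighted use the amplitude-weighted resultant
#' @return data.frame `rel_time, R, p, n`
#' @export
phase_alignment <- function(ens, weighted = FALSE) {
  out <- lapply(seq_along(ens$rel_times), function(j) {
    mr <- mean_resultant(ens$phase[, j],
                         amp = if (weighted) ens$amp[, j] else NULL)
    data.frame(rel_time = ens$rel_times[j], R = mr$R, p = mr$p, n = mr$n)
  })
  do.call(rbind, out)
}

# Fisher-Lee circular-circular correlation.
circ_cor <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3L) return(NA_real_)
  num <- 0; d1 <- 0; d2 <- 0
  sa <- sin(outer(a, a, `-`))
  sb <- sin(outer(b, b, `-`))
  iu <- upper.tri(sa)
  sum(sa[iu] * sb[iu]) / sqrt(sum(sa[iu]^2) * sum(sb[iu]^2))
}

#' Theta phase-transition (reset vs shift) analysis
#'
#' Compares pre- and post-stimulus theta phase using two non-overlapping
#' STFT windows: the pre window ends at stimulus onset (frame centred at
#' `onset - window/2`) and the post window starts 100 ms after onset (frame
#' centred at `onset + 0.1 + window/2`), so the two estimates derive from
#' independent data segments. Each estimate is extrapolated to the midpoint
#' of the 100 ms gap (onset + 50 ms) with its own frequency:
#' `phi_ref = phi + 2*pi*f*dt`, wrapped. For the US the post window starts
#' 100 ms after US offset and phases are extrapolated to US onset + 50 ms.
#'
#' A diagonal point cloud (circular correlation near 1, mean shift near 0)
#' means the rhythm is unaffected; a horizontal cloud (post phase
#' concentrated regardless of pre) means a reset to a fixed phase; a
#' displaced diagonal means a constant phase shift.
#'
#' @param lfp single-channel [eb_timeseries()]
#' @param trials trial table
#' @param stimulus `"CS"` or `"US"`
#' @param window_length STFT window in s
#' @param gap gap between the windows in s (default 0.1)
#' @param band theta band in Hz
#' @return `eb_phase_transition`: per-trial data.frame (`pre, post, shift`,
#'   radians at the reference time), summary (`circ_cor`, `mean_shift`,
#'   `shift_R`, `post_R`, `post_rayleigh_p`, `n`), and the excluded-trial
#'   count
#' @export
phase_transition <- function(lfp, trials, stimulus = c("CS", "US"),
                             window_length = 0.4, gap = 0.1,
                             band = c(4, 12)) {
  stimulus <- match.arg(stimulus)
  onset <- if (stimulus == "CS") trials$cs_onset else trials$us_onset
  post_start <- if (stimulus == "CS") onset + gap
                else onset + trials$us_duration + gap
  t_ref <- onset + gap / 2
  pre_c <- onset - window_length / 2
  post_c <- post_start + window_length / 2
  s_pre <- stft(lfp, window_length = window_length, times = pre_c)
  s_post <- stft(lfp, window_length = window_length, times = post_c)
  pk_pre <- stft_peak(s_pre, band[1], band[2])
  pk_post <- stft_peak(s_post, band[1], band[2])
  pre <- wrap_phase(pk_pre$phase + 2 * pi * pk_pre$freq * (t_ref - pre_c))
  post <- wrap_phase(pk_post$phase + 2 * pi * pk_post$freq * (t_ref - post_c))
  ok <- is.finite(pre) & is.finite(post)
  shift <- wrap_phase(post - pre)
  mr_shift <- mean_resultant(shift[ok])
  mr_post <- mean_resultant(post[ok])
  structure(list(trials = data.frame(trial = trials$trial, pre = pre,
                                     post = post, shift = shift, valid = ok),
                 summary = list(circ_cor = circ_cor(pre[ok], post[ok]),
                                mean_shift = mr_shift$mean_phase,
                                shift_R = mr_shift$R,
                                post_R = mr_post$R,
                                post_rayleigh_p = mr_post$p,
                                n = sum(ok)),
                 n_excluded = sum(!ok), stimulus = stimulus),
            class = "eb_phase_transition")
}

#' @export
print.eb_phase_transition <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<eb_phase_transition> %s, %d trial(s) (%d excluded)\n  circular cor %.3f; mean shift %.3f rad (R = %.2f); post R = %.2f (Rayleigh p = %.3g)\n",
    x$stimulus, s$n, x$n_excluded, s$circ_cor, s$mean_shift, s$shift_R,
    s$post_R, s$post_rayleigh_p))
  invisible(x)
}

#' @export
plot.eb_phase_transition <- function(x, ...) {
  ok <- x$trials$valid
  graphics::plot(x$trials$pre[ok], x$trials$post[ok], pch = 16, cex = 0.6,
                 xlab = "pre-stimulus phase (rad)",
                 ylab = "post-stimulus phase (rad)",
                 xlim = c(-pi, pi), ylim = c(-pi, pi), ...)
  graphics::abline(0, 1, lty = 3)
}

#' Classify pre-trial LFP state
#'
#' Three-way classification driving the theta stratification: `run_theta`
#' for running trials; sitting trials are `sit_theta` when the pre-trial
#' theta (4-12 Hz) to delta (1-4 Hz) power ratio exceeds 4 and the theta
#' power exceeds the 5th percentile of running theta power, else
#' `sit_nontheta`.
#'
#' @param lfp single-channel [eb_timeseries()]
#' @param trials trial table
#' @param states per-trial locomotor labels from [classify_trial_state()]
#' @param run_theta_ref numeric vector of theta power observed during
#'   running (reference distribution), e.g. from the run trials' pre-trial
#'   windows
#' @param pre_window pre-trial window length in s (default 1)
#' @param ratio_thresh theta/delta ratio threshold
#' @return character per trial: `run_theta`, `sit_theta`, `sit_nontheta`, or
#'   `unclassified`
#' @export
classify_trial_lfp_state <- function(lfp, trials, states,
                                     run_theta_ref = NULL, pre_window = 1,
                                     ratio_thresh = 4) {
  n <- nrow(trials)
  theta_p <- delta_p <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    ctr <- trials$cs_onset[k] - pre_window / 2
    s <- tryCatch(stft(lfp, window_length = pre_window, times = ctr),
                  error = function(e) NULL)
    if (is.null(s) || !s$valid[1]) next
    theta_p[k] <- stft_band_power(s, 4, 12)
    delta_p[k] <- stft_band_power(s, 1, 4)
  }
  if (is.null(run_theta_ref)) run_theta_ref <- theta_p[states == "run"]
  ref5 <- stats::quantile(run_theta_ref, 0.05, na.rm = TRUE, names = FALSE)
  out <- rep("unclassified", n)
  ok <- is.finite(theta_p) & is.finite(delta_p)
  out[ok & states == "run"] <- "run_theta"
  sit <- ok & states == "sit"
  is_theta <- sit & theta_p / delta_p > ratio_thresh & theta_p > ref5
  out[is_theta] <- "sit_theta"
  out[sit & !is_theta] <- "sit_nontheta"
  out
}

# Circular-linear correlation between phase and a linear variable: the
# magnitude follows the standard embedding formula, and the sign is the sign
# of the best-fitting phase-position slope (grid maximisation of the
# resultant of phase - 2*pi*a*x, the usual precession-slope estimator).
circ_lin_cor <- function(phase, x, slope_range = c(-0.5, 0.5)) {
  ok <- is.finite(phase) & is.finite(x)
  phase <- phase[ok]; x <- x[ok]
  if (length(x) < 5L) return(NA_real_)
  rxc <- stats::cor(x, cos(phase))
  rxs <- stats::cor(x, sin(phase))
  rcs <- stats::cor(cos(phase), sin(phase))
  r <- sqrt((rxc^2 + rxs^2 - 2 * rxc * rxs * rcs) / (1 - rcs^2))
  a_hat <- circ_lin_slope(phase, x, slope_range)
  r * if (a_hat < 0) -1 else 1
}

# Phase-position slope (cycles per cm) maximising the resultant of
# phase - 2*pi*a*x.
circ_lin_slope <- function(phase, x, slope_range = c(-0.5, 0.5)) {
  grid <- seq(slope_range[1], slope_range[2], length.out = 201)
  resv <- vapply(grid, function(a) Mod(mean(exp(1i * (phase - 2 * pi * a * x)))),
                 numeric(1))
  grid[which.max(resv)]
}

#' Phase-precession overlay around eyeblink trials
#'
#' Pairs each spike's theta phase with the animal's position, labelled by
#' whether the spike fell within `proximity` of a CS or US onset. Summary:
#' the circular-linear trend of phase on position (all spikes) and a
#' Watson-Wilcoxon-style rank comparison of the phase-given-position
#' residuals between labels.
#'
#' @param spikes spike-time vector
#' @param traj an `eb_trajectory`
#' @param lfp single-channel [eb_timeseries()] for phase extraction
#' @param trials trial table (may be empty)
#' @param proximity seconds around CS/US onsets labelling a spike
#'   trial-proximal
#' @param field_range optional `c(lo, hi)` track interval restricting spikes
#'   to the cell's field
#' @return `eb_precession`: data.frame `t, x, phase, near_trial`, plus
#'   `trend` (circular-linear correlation) and `label_p` (two-sample
#'   Wilcoxon p on residual phases; `NA` if either label is empty)
#' @export
phase_precession_overlay <- function(spikes, traj, lfp, trials = NULL,
                                     proximity = 0.5, field_range = NULL) {
  df <- traj$traj
  keep <- spikes >= min(df$t) & spikes <= max(df$t)
  spikes <- spikes[keep]
  xi <- stats::approx(df$t, df$x, xout = spikes)$y
  if (!is.null(field_range)) {
    sel <- xi >= field_range[1] & xi <= field_range[2]
    spikes <- spikes[sel]; xi <- xi[sel]
  }
  if (!length(spikes))
    return(structure(list(spikes = data.frame(t = numeric(0), x = numeric(0),
                                              phase = numeric(0),
                                              near_trial = logical(0)),
                          trend = NA_real_, label_p = NA_real_),
                     class = "eb_precession"))
  s <- stft(lfp, window_length = 0.4, times = spikes)
  pk <- stft_peak(s, 4, 12)
  near <- rep(FALSE, length(spikes))
  if (!is.null(trials) && nrow(trials)) {
    for (k in seq_len(nrow(trials))) {
      near <- near | (abs(spikes - trials$cs_onset[k]) <= proximity) |
        (abs(spikes - trials$us_onset[k]) <= proximity)
    }
  }
  ok <- is.finite(pk$phase)
  phase <- pk$phase
  trend <- circ_lin_cor(phase[ok], xi[ok])
  # residual phases about the fitted precession line, compared across labels
  label_p <- NA_real_
  if (any(near[ok]) && any(!near[ok]) && sum(ok) >= 10L) {
    a_hat <- circ_lin_slope(phase[ok], xi[ok])
    res <- wrap_phase(phase[ok] - 2 * pi * a_hat * xi[ok])
    res <- wrap_phase(res - mean_resultant(res)$mean_phase)
    label_p <- suppressWarnings(
      stats::wilcox.test(res[near[ok]], res[!near[ok]])$p.value)
  }
  structure(list(spikes = data.frame(t = spikes, x = xi, phase = phase,
                                     near_trial = near),
                 trend = trend, label_p = label_p),
            class = "eb_precession")
}

#' @export
print.eb_precession <- function(x, ...) {
  cat(sprintf("<eb_precession> %d spike(s), trend %.3f, label p = %s\n",
              nrow(x$spikes), x$trend,
              ifelse(is.na(x$label_p), "NA", sprintf("%.3g", x$label_p))))
  invisible(x)
}
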