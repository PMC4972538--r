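# Ripple detection on multi-channel LFP and peri-stimulus ripple statistics.

# Sliding RMS of a vector over a window of w samples (centred, boxcar).
sliding_rms <- function(v, w) {
  w <- max(1L, w)
  w <- w + (1L - w %% 2L)
  p <- (w - 1L) %/% 2L
  vp <- c(rep(v[1L]^2, p), v^2, rep(v[length(v)]^2, p))
  sqrt(as.numeric(stats::filter(vp, rep(1 / w, w), sides = 2L))[p + seq_along(v)])
}

# Candidate events on one channel: contiguous regions of band-RMS above the
# peak threshold, extended to the crossings of the lower (edge) threshold.
channel_candidates <- function(rms, fs, thr_peak, thr_edge, dur_bounds) {
  above <- rms > thr_peak
  if (!any(above)) return(data.frame(t = numeric(0), duration = numeric(0),
                                     amp = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  ps <- starts[r$values]
  pe <- ends[r$values]
  low <- rms > thr_edge
  out <- vector("list", length(ps))
  for (i in seq_along(ps)) {
    a <- ps[i]
    while (a > 1L && low[a - 1L]) a <- a - 1L
    b <- pe[i]
    while (b < length(rms) && low[b + 1L]) b <- b + 1L
    pk <- a - 1L + which.max(rms[a:b])
    out[[i]] <- c(t = (pk - 1L) / fs, t_start = (a - 1L) / fs,
                  t_end = (b - 1L) / fs, amp = rms[pk])
  }
  df <- as.data.frame(do.call(rbind, out))
  df$duration <- df$t_end - df$t_start
  df <- df[!duplicated(round(df$t_start * fs)), , drop = FALSE]
  df[df$duration >= dur_bounds[1] & df$duration <= dur_bounds[2], , drop = FALSE]
}

#' Detect ripples on a multi-channel LFP
#'
#' Each channel is band-passed to 80-250 Hz and its sliding RMS scanned for
#' peaks above a per-channel threshold (mean + `threshold_sd` SDs, computed
#' over `baseline_mask` samples if given, otherwise the whole trace). Each
#' candidate's frequency is estimated from a short STFT frame centred on the
#' peak; candidates are kept iff the frequency lies in 120-250 Hz and the
#' event is coincident (within `coincidence` seconds) on at least
#' `min_channels` channels. Overlapping accepted events are merged, keeping
#' the longest-duration member of each cluster.
#'
#' @param lfp a multi-channel [eb_timeseries()] (or an `eb_lfp`); sample
#'   rate >= 600 Hz, >= 3 channels
#' @param threshold_sd peak threshold in SDs above the mean band RMS
#' @param edge_sd event-extent threshold in SDs
#' @param min_channels minimum coincident channels (>= 3)
#' @param coincidence cross-channel coincidence window in s
#' @param rms_window sliding RMS window in s
#' @param duration_bounds admissible event durations in s
#' @param freq_band band for the pass filter in Hz
#' @param freq_accept acceptance band for the event frequency in Hz
#' @param stft_frame STFT frame length for frequency estimation in s
#' @param baseline_mask optional logical per sample for threshold estimation
#' @return `eb_ripples`: data.frame `t, duration, freq, n_channels, amp`,
#'   plus the detection parameters
#' @export
detect_ripples <- function(lfp, threshold_sd = 5, edge_sd = 2,
                           min_channels = 3L, coincidence = 0.015,
                           rms_window = 0.01, duration_bounds = c(0.02, 0.2),
                           freq_band = c(80, 250), freq_accept = c(120, 250),
                           stft_frame = 0.1, baseline_mask = NULL) {
  if (inherits(lfp, "eb_lfp")) lfp <- lfp$lfp
  stopifnot(inherits(lfp, "eb_timeseries"))
  if (ts_nchan(lfp) < 3L)
    stop("ripple detection requires at least 3 channels")
  if (min_channels < 3L) stop("min_channels must be at least 3")
  if (lfp$fs < 600) stop("sample rate must be at least 600 Hz")
  nch <- ts_nchan(lfp)
  fb <- bandpass(lfp, freq_band[1], freq_band[2])
  cands <- vector("list", nch)
  for (ch in seq_len(nch)) {
    v <- fb$samples[, ch]
    rms <- sliding_rms(v, round(rms_window * lfp$fs))
    ref <- if (is.null(baseline_mask)) rms else rms[baseline_mask]
    mu <- mean(ref); sdv <- stats::sd(ref)
    cands[[ch]] <- channel_candidates(rms, lfp$fs, mu + threshold_sd * sdv,
                                      mu + edge_sd * sdv, duration_bounds)
  }
  # frequency check on the channel with the candidate, then coincidence count
  events <- list()
  for (ch in seq_len(nch)) {
    cd <- cands[[ch]]
    if (!nrow(cd)) next
    xs <- ts_channel(fb, ch)
    for (i in seq_len(nrow(cd))) {
      tc <- cd$t[i] + lfp$t0
      s <- tryCatch(stft(xs, window_length = stft_frame, times = tc,
                         zero_pad = 4), error = function(e) NULL)
      if (is.null(s) || !s$valid[1]) next
      pk <- stft_peak(s, freq_band[1], freq_band[2])
      if (!is.finite(pk$freq[1]) || pk$freq[1] < freq_accept[1] ||
          pk$freq[1] > freq_accept[2]) next
      nco <- sum(vapply(seq_len(nch), function(c2)
        nrow(cands[[c2]]) > 0 && any(abs(cands[[c2]]$t - cd$t[i]) <= coincidence),
        logical(1)))
      if (nco < min_channels) next
      events[[length(events) + 1L]] <- data.frame(
        t = tc, t_start = cd$t_start[i] + lfp$t0, t_end = cd$t_end[i] + lfp$t0,
        duration = cd$duration[i], freq = pk$freq[1], n_channels = nco,
        amp = cd$amp[i])
    }
  }
  if (!length(events)) {
    ev <- data.frame(t = numeric(0), duration = numeric(0), freq = numeric(0),
                     n_channels = integer(0), amp = numeric(0))
  } else {
    ev <- do.call(rbind, events)
    ev <- ev[order(ev$t), ]
    # merge overlapping detections across channels: keep the longest per cluster
    cluster <- cumsum(c(1, diff(ev$t) > coincidence * 2))
    keep <- vapply(split(seq_len(nrow(ev)), cluster),
                   function(ix) ix[which.max(ev$duration[ix])], integer(1))
    ev <- ev[keep, c("t", "duration", "freq", "n_channels", "amp")]
    rownames(ev) <- NULL
  }
  structure(list(events = ev,
                 params = list(threshold_sd = threshold_sd, edge_sd = edge_sd,
                               min_channels = min_channels,
                               coincidence = coincidence,
                               rms_window = rms_window,
                               duration_bounds = duration_bounds,
                               freq_band = freq_band,
                               freq_accept = freq_accept)),
            class = "eb_ripples")
}

#' @export
print.eb_ripples <- function(x, ...) {
  cat(sprintf("<eb_ripples> %d event(s)\n", nrow(x$events)))
  invisible(x)
}

#' Peri-stimulus ripple occurrence rate
#'
#' Events per second in bins relative to CS onset, computed separately per
#' trial state (run-state trials are expected near zero: ripples do not
#' occur during running).
#'
#' @param events ripple event data.frame (`t`) or an `eb_ripples`
#' @param trials trial table
#' @param states per-trial state labels (see [classify_trial_state()]); a
#'   single label is recycled
#' @param t_range peri-CS window in s
#' @param binwidth bin width in s
#' @return list per state: `bin_centers`, `rate` (events/s), `n_trials`
#' @export
ripple_rate <- function(events, trials, states = "all", t_range = c(-2, 2),
                        binwidth = 0.25) {
  if (inherits(events, "eb_ripples")) events <- events$events
  states <- rep(as.character(states), length.out = nrow(trials))
  edges <- seq(t_range[1], t_range[2], by = binwidth)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  out <- list()
  for (s in unique(states)) {
    sel <- which(states == s)
    rel <- unlist(lapply(trials$cs_onset[sel], function(cs) {
      r <- events$t - cs
      r[r >= t_range[1] & r < t_range[2]]
    }))
    cnt <- bin_counts(rel, edges)
    out[[s]] <- list(bin_centers = centers,
                     rate = cnt / (length(sel) * binwidth),
                     n_trials = length(sel))
  }
  out
}

#' Split trials by pre-CS ripple presence
#'
#' Partitions trials by whether at least one ripple peak falls in the
#' half-open pre-CS window `[cs - pre_window, cs)`; an event exactly at CS
#' onset is excluded.
#'
#' @param events ripple event data.frame or `eb_ripples`
#' @param trials trial table
#' @param pre_window pre-CS window length in s
#' @return list with integer trial indices `ripple` and `no_ripple`, and the
#'   per-trial logical `has_ripple`
#' @export
split_trials_by_ripple <- function(events, trials, pre_window = 2) {
  if (inherits(events, "eb_ripples")) events <- events$events
  has <- vapply(trials$cs_onset, function(cs)
    any(events$t >= cs - pre_window & events$t < cs), logical(1))
  list(ripple = which(has), no_ripple = which(!has), has_ripple = has)
}
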