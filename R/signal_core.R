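# Shared signal-processing primitives: zero-phase band-pass filtering,
# windowed RMS, and the locality-guaranteed short-time Fourier transform on
# which the ripple and theta modules are built.

#' Zero-phase FIR band-pass filter
#'
#' Window-method FIR band-pass applied forward and backward so the output has
#' zero phase distortion. The filter order is chosen from the transition-band
#' rule of thumb for a Hamming window (about `3.3 * fs / transition`), which
#' gives well over 40 dB of stop-band attenuation after the two passes. Edges
#' are handled by reflection padding of one filter length so the output has
#' the same length as the input.
#'
#' @param x an [eb_timeseries()] (single- or multi-channel)
#' @param low,high band edges in Hz; `0 < low < high < fs/2`
#' @param transition transition-band width in Hz used to set the filter
#'   order; default one quarter of `low`, at least 10 Hz
#' @return filtered `eb_timeseries` with the same length and channels
#' @examples
#' fs <- 1000
#' x <- eb_timeseries(sin(2 * pi * 150 * seq(0, 1, by = 1/fs)), fs)
#' y <- bandpass(x, 80, 250)
#' @export
bandpass <- function(x, low, high, transition = NULL) {
  stopifnot(inherits(x, "eb_timeseries"))
  ny <- x$fs / 2
  if (!is.finite(low) || !is.finite(high) || low <= 0 || high <= low || high >= ny)
    stop(sprintf("invalid band edges: need 0 < low < high < fs/2 = %g Hz", ny))
  if (is.null(transition)) transition <- max(10, low / 4)
  n <- ceiling(3.3 * x$fs / transition)
  n <- n + n %% 2L                      # even order => odd-length symmetric FIR
  fir <- signal::fir1(n, c(low, high) / ny, type = "pass")
  filt1 <- function(v) {
    np <- min(length(v) - 1L, 3L * (n + 1L))
    vp <- c(2 * v[1L] - v[(np + 1L):2L],
            v,
            2 * v[length(v)] - v[(length(v) - 1L):(length(v) - np)])
    y <- signal::filtfilt(fir, vp)
    y[np + seq_along(v)]
  }
  smp <- if (is.matrix(x$samples)) apply(x$samples, 2L, filt1) else filt1(x$samples)
  eb_timeseries(smp, x$fs, x$t0)
}

#' Root-mean-square amplitude over a time window
#'
#' RMS of the samples falling in `[t_start, t_end)`.
#'
#' @param x a single-channel [eb_timeseries()]
#' @param t_start,t_end window in seconds, inside the series extent
#' @return RMS amplitude (same units as the samples)
#' @export
windowed_rms <- function(x, t_start, t_end) {
  stopifnot(inherits(x, "eb_timeseries"))
  if (t_end <= t_start) stop("empty window: t_end must exceed t_start")
  tt <- ts_times(x)
  if (t_start < x$t0 - 0.5 / x$fs || t_end > x$t0 + ts_duration(x) + 0.5 / x$fs)
    stop("window extends beyond the series extent")
  keep <- tt >= t_start & tt < t_end
  if (!any(keep)) stop("window contains no samples")
  sqrt(mean(x$samples[keep]^2))
}

#' Locality-guaranteed short-time Fourier transform
#'
#' STFT whose coefficient at time `t` is computed from samples within
#' `t +/- window_length/2` only: frames that would extend past either end of
#' the series are marked invalid (`NA`) rather than padded, so no estimate is
#' ever influenced by data outside its declared window. The default window is
#' a 400 ms Kaiser window with shape parameter alpha = 1 (beta = pi), so
#' theta-band estimates depend on at most +/- 200 ms of data. Coefficients
#' use a time origin at the frame centre: for `x = cos(2*pi*f*t + phi)` the
#' argument of the coefficient at frequency `f` is the instantaneous phase
#' `2*pi*f*t + phi` at the frame centre.
#'
#' @param x a single-channel [eb_timeseries()]
#' @param window_length window length in seconds (default 0.4)
#' @param hop frame step in seconds (default 0.01)
#' @param kaiser_alpha Kaiser shape alpha; `beta = pi * alpha` (default 1)
#' @param zero_pad zero-padding factor for frequency interpolation (default 4)
#' @param times optional explicit frame-centre times (seconds); overrides `hop`
#' @return an `eb_stft` object: `times` (s), `freqs` (Hz), complex coefficient
#'   matrix `coef` (frames x frequencies, `NA` rows for invalid frames),
#'   `valid` logical per frame, plus window metadata
#' @export
stft <- function(x, window_length = 0.4, hop = 0.01, kaiser_alpha = 1,
                 zero_pad = 4, times = NULL) {
  stopifnot(inherits(x, "eb_timeseries"))
  if (is.matrix(x$samples)) stop("stft() expects a single channel; use ts_channel()")
  if (!is.null(hop) && hop <= 0) stop("hop must be positive")
  n_win <- round(window_length * x$fs)
  n_win <- n_win + (1L - n_win %% 2L)       # odd length, symmetric about centre
  if (n_win > ts_nsamp(x)) stop("window_length exceeds the series length")
  half <- (n_win - 1L) %/% 2L
  if (is.null(times)) {
    times <- seq(x$t0, x$t0 + (ts_nsamp(x) - 1L) / x$fs, by = hop)
  }
  centres <- round((times - x$t0) * x$fs) + 1L
  valid <- centres - half >= 1L & centres + half <= ts_nsamp(x)
  win <- signal::kaiser(n_win, pi * kaiser_alpha)
  nfft <- 2L * ceiling(zero_pad * n_win / 2)
  nf <- nfft %/% 2L + 1L
  freqs <- (0:(nf - 1L)) * x$fs / nfft
  coef <- matrix(NA_complex_, nrow = length(times), ncol = nf)
  vi <- which(valid)
  if (length(vi)) {
    # frame matrix: one column per valid frame
    idx <- outer(-half:half, centres[vi], `+`)
    frames <- matrix(x$samples[idx], nrow = n_win) * win
    frames <- rbind(frames, matrix(0, nfft - n_win, ncol(frames)))
    ft <- stats::mvfft(frames)[seq_len(nf), , drop = FALSE]
    # shift time origin to the frame centre
    rot <- exp(2i * pi * (0:(nf - 1L)) * half / nfft)
    coef[vi, ] <- t(ft * rot)
  }
  structure(list(times = times, freqs = freqs, coef = coef, valid = valid,
                 window_length = n_win / x$fs, window = "kaiser",
                 kaiser_alpha = kaiser_alpha, fs = x$fs, nfft = nfft,
                 win_energy = sum(win^2)),
            class = "eb_stft")
}

#' @export
print.eb_stft <- function(x, ...) {
  cat(sprintf("<eb_stft> %d frame(s) (%d valid), %d frequencies up to %g Hz, %s window %.0f ms\n",
              length(x$times), sum(x$valid), length(x$freqs), max(x$freqs),
              x$window, 1000 * x$window_length))
  invisible(x)
}

#' Band power from an STFT
#'
#' Total squared modulus over the frequency bins inside `[low, high]`, per
#' frame. Used for theta/delta ratios and ripple frequency checks.
#'
#' @param s an `eb_stft`
#' @param low,high band in Hz
#' @return numeric vector, one value per frame (`NA` for invalid frames)
#' @export
stft_band_power <- function(s, low, high) {
  sel <- s$freqs >= low & s$freqs <= high
  rowSums(Mod(s$coef[, sel, drop = FALSE])^2)
}

# Peak frequency in [low, high] per frame, with quadratic interpolation of
# log-power around the argmax bin. Returns list(freq, phase, amp) where phase
# and amplitude are read from the argmax bin.
stft_peak <- function(s, low, high) {
  sel <- which(s$freqs >= low & s$freqs <= high)
  if (length(sel) < 3L) stop("band too narrow for the frequency resolution")
  p <- Mod(s$coef[, sel, drop = FALSE])^2
  n <- length(s$times)
  freq <- phase <- amp <- rep(NA_real_, n)
  df <- s$freqs[2L] - s$freqs[1L]
  for (i in seq_len(n)) {
    if (!s$valid[i]) next
    j <- which.max(p[i, ])
    f0 <- s$freqs[sel[j]]
    if (j > 1L && j < length(sel)) {
      lp <- log(pmax(p[i, (j - 1L):(j + 1L)], .Machine$double.xmin))
      den <- lp[1L] - 2 * lp[2L] + lp[3L]
      if (is.finite(den) && den < 0) {
        delta <- 0.5 * (lp[1L] - lp[3L]) / den
        f0 <- f0 + max(-0.5, min(0.5, delta)) * df
      }
    }
    freq[i] <- f0
    phase[i] <- Arg(s$coef[i, sel[j]])
    amp[i] <- Mod(s$coef[i, sel[j]])
  }
  list(freq = freq, phase = phase, amp = amp)
}

# Counts per half-open bin [e_i, e_{i+1}) (last bin closed); robust to empty
# input, values outside the edges are dropped.
bin_counts <- function(x, edges) {
  x <- x[is.finite(x) & x >= edges[1] & x <= edges[length(edges)]]
  if (!length(x)) return(integer(length(edges) - 1L))
  tabulate(findInterval(x, edges, rightmost.closed = TRUE),
           nbins = length(edges) - 1L)
}

#' Wrap angles to (-pi, pi]
#' @param theta angles in radians
#' @return wrapped angles
#' @export
wrap_phase <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}
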