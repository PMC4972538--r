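#' Uniformly sampled time series
#'
#' Light container for LFP/EMG-style traces: a numeric sample vector (or a
#' samples x channels matrix for multi-channel data), a sample rate in Hz and
#' the time of the first sample in seconds. All signal-processing operations
#' in the package consume and return this class.
#'
#' @param samples numeric vector, or matrix with one column per channel
#' @param fs sample rate in Hz (> 0)
#' @param t0 time of the first sample in seconds
#' @return an object of class `eb_timeseries`
#' @examples
#' x <- eb_timeseries(sin(2 * pi * 8 * seq(0, 1, by = 1/500)), fs = 500)
#' ts_duration(x)
#' @export
eb_timeseries <- function(samples, fs, t0 = 0) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  if (is.matrix(samples)) {
    if (nrow(samples) < 1L) stop("`samples` must contain at least one sample")
  } else {
    samples <- as.numeric(samples)
    if (length(samples) < 1L) stop("`samples` must contain at least one sample")
  }
  structure(list(samples = samples, fs = fs, t0 = t0),
            class = "eb_timeseries")
}

ts_nsamp <- function(x) if (is.matrix(x$samples)) nrow(x$samples) else length(x$samples)

ts_nchan <- function(x) if (is.matrix(x$samples)) ncol(x$samples) else 1L

#' @rdname eb_timeseries
#' @param x an `eb_timeseries`
#' @export
ts_times <- function(x) x$t0 + (seq_len(ts_nsamp(x)) - 1L) / x$fs

#' @rdname eb_timeseries
#' @export
ts_duration <- function(x) ts_nsamp(x) / x$fs

#' Extract one channel of a multi-channel series
#' @param x an `eb_timeseries`
#' @param i channel index
#' @return a single-channel `eb_timeseries`
#' @export
ts_channel <- function(x, i) {
  if (!is.matrix(x$samples)) {
    if (i != 1L) stop("series has a single channel")
    return(x)
  }
  eb_timeseries(x$samples[, i], x$fs, x$t0)
}

#' Crop a time series to a time interval
#' @param x an `eb_timeseries`
#' @param t_start,t_end interval in seconds; samples with `t_start <= t < t_end`
#' @return cropped `eb_timeseries`
#' @export
ts_crop <- function(x, t_start, t_end) {
  tt <- ts_times(x)
  keep <- tt >= t_start & tt < t_end
  if (!any(keep)) stop("crop interval contains no samples")
  smp <- if (is.matrix(x$samples)) x$samples[keep, , drop = FALSE] else x$samples[keep]
  eb_timeseries(smp, x$fs, tt[which(keep)[1L]])
}

#' @export
print.eb_timeseries <- function(x, ...) {
  cat(sprintf("<eb_timeseries> %d sample(s), %d channel(s), %g Hz, t = [%.3f, %.3f) s\n",
              ts_nsamp(x), ts_nchan(x), x$fs, x$t0, x$t0 + ts_duration(x)))
  invisible(x)
}

#' @export
plot.eb_timeseries <- function(x, channel = 1L, ...) {
  graphics::plot(ts_times(x), ts_channel(x, channel)$samples, type = "l",
                 xlab = "time (s)", ylab = "amplitude", ...)
}
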