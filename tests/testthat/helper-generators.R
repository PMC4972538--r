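# Shared synthetic LFP generators for the ripple and theta tests.

# noise LFP with wavelets injected at known times on a channel subset
make_ripple_lfp <- function(duration = 60, fs = 1000, n_ch = 4,
                            inject_t = numeric(0), freq = 150, dur = 0.05,
                            amp = 8, channels = seq_len(n_ch), seed = 51) {
  set.seed(seed)
  n <- duration * fs
  smp <- matrix(rnorm(n * n_ch), n, n_ch)
  for (t0 in inject_t) {
    idx <- round((t0 - dur) * fs):round((t0 + dur) * fs)
    idx <- idx[idx >= 1 & idx <= n]
    tau <- (idx - 1) / fs - t0
    wav <- amp * exp(-tau^2 / (2 * (dur / 4)^2)) * cos(2 * pi * freq * tau)
    for (ch in channels) smp[idx, ch] <- smp[idx, ch] + wav
  }
  eb_timeseries(smp, fs)
}

# LFP whose theta phase is fully specified: phi(t) piecewise, with optional
# per-trial reset/shift at the CS onsets.
make_theta_lfp <- function(cs, fs = 1000, duration = NULL, f0 = 8,
                           mode = c("unbroken", "reset", "shift"),
                           reset_phase = 1, shift = pi / 4, noise_sd = 0.05,
                           seed = 61) {
  mode <- match.arg(mode)
  if (is.null(duration)) duration <- max(cs) + 3
  set.seed(seed)
  n <- duration * fs
  t <- (0:(n - 1)) / fs
  phi0 <- runif(1, -pi, pi)
  phi <- 2 * pi * f0 * t + phi0
  for (c0 in cs) {
    after <- t >= c0
    if (mode == "reset") {
      phi[after] <- reset_phase + 2 * pi * f0 * (t[after] - c0)
    } else if (mode == "shift") {
      phi[after] <- phi[after] + shift
    }
    # fresh pre-CS phase for the next trial: re-randomize well after this one
    if (mode != "unbroken") {
      far <- t >= c0 + 2
      phi[far] <- phi[far] + runif(1, -pi, pi)
    }
  }
  eb_timeseries(cos(phi) + rnorm(n, 0, noise_sd), fs)
}
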