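# Occupancy-normalized place-field maps, spatial classification, and the
# per-trial place-field intensity statistic.

# Truncated-Gaussian smoothing (kernel cut at 4 sigma) of a vector with a
# validity mask: invalid bins contribute nothing and the kernel is
# renormalized over the contributing bins.
smooth_masked_1d <- function(v, valid, sigma_bins) {
  if (sigma_bins <= 0) return(v)
  hw <- max(1L, ceiling(4 * sigma_bins))
  k <- stats::dnorm(-hw:hw, sd = sigma_bins)
  vv <- ifelse(valid, v, 0)
  w <- as.numeric(valid)
  n <- length(v)
  pad <- function(z) c(rep(0, hw), z, rep(0, hw))
  num <- stats::filter(pad(vv), k, sides = 2L)[hw + seq_len(n)]
  den <- stats::filter(pad(w), k, sides = 2L)[hw + seq_len(n)]
  out <- ifelse(den > 0, num / den, NA_real_)
  as.numeric(out)
}

smooth_masked_2d <- function(m, valid, sigma_bins) {
  if (sigma_bins <= 0) return(m)
  num <- ifelse(valid, m, 0)
  den <- matrix(as.numeric(valid), nrow(m), ncol(m))
  # separable convolution with an unnormalized kernel applied to num and den
  hw <- max(1L, ceiling(4 * sigma_bins))
  k <- stats::dnorm(-hw:hw, sd = sigma_bins)
  conv1 <- function(v) {
    pad <- c(rep(0, hw), v, rep(0, hw))
    as.numeric(stats::filter(pad, k, sides = 2L))[hw + seq_along(v)]
  }
  cnum <- apply(apply(num, 2L, conv1), 1L, conv1)
  cden <- apply(apply(den, 2L, conv1), 1L, conv1)
  out <- ifelse(t(cden) > 0, t(cnum) / t(cden), NA_real_)
  matrix(out, nrow(m), ncol(m))
}

#' Build an occupancy-normalized place-field map
#'
#' Track maps are one-dimensional, computed independently per running
#' direction, and smoothed with a 3 cm Gaussian; endbox maps are
#' two-dimensional, non-directional, smoothed with 1 cm. Only samples with
#' speed above `v_thresh` (2 cm/s) contribute, the 2 s window after every CS
#' onset is excluded from both spike and occupancy counts, and bins with
#' occupancy below `occ_min` (50 ms per cm^2 of bin area) are invalid.
#' Spike-count and occupancy maps are smoothed separately, respecting the
#' validity mask, then divided.
#'
#' @param spikes numeric vector of spike times in s
#' @param traj an `eb_trajectory`
#' @param trials trial table (for the post-CS exclusion), or `NULL`
#' @param bin_track,bin_box bin sizes in cm
#' @param sigma_track,sigma_box smoothing sigma in cm (0 disables)
#' @param v_thresh moving-speed threshold in cm/s
#' @param cs_exclusion seconds excluded after each CS onset
#' @param occ_min occupancy validity threshold in s/cm^2
#' @return an `eb_ratemap`: per-direction track maps (`centers`, `rate`,
#'   `raw`, `occupancy`, `valid`) and per-side endbox maps (matrices), the
#'   spike count used, and the parameters
#' @export
build_rate_map <- function(spikes, traj, trials = NULL, bin_track = 1,
                           bin_box = 1, sigma_track = 3, sigma_box = 1,
                           v_thresh = 2, cs_exclusion = 2, occ_min = 0.05) {
  stopifnot(inherits(traj, "eb_trajectory"))
  env <- traj$env
  df <- traj$traj
  fs <- traj$fs
  dt <- 1 / fs
  sp <- estimate_speed(traj)
  keep <- sp > v_thresh
  if (!is.null(trials) && nrow(trials)) {
    for (cs in trials$cs_onset)
      keep <- keep & !(df$t >= cs & df$t < cs + cs_exclusion)
  }
  if (!any(keep)) warning("no moving occupancy; the map is entirely invalid")
  # direction per sample from smoothed x velocity
  n <- nrow(df)
  xs <- df$x
  vx <- (xs[c(2:n, n)] - xs[c(1, 1:(n - 1))]) /
    (df$t[c(2:n, n)] - df$t[c(1, 1:(n - 1))])
  dir <- ifelse(vx > 0, "rightward", "leftward")
  region <- position_region(env, df$x, df$y)

  # assign spikes to the nearest trajectory sample
  si <- pmin(n, pmax(1L, round((spikes - df$t[1]) * fs) + 1L))
  spike_keep <- keep[si]
  used <- sum(spike_keep)

  track_edges <- seq(0, env$track_length, by = bin_track)
  centers <- (track_edges[-1] + track_edges[-length(track_edges)]) / 2
  mk_track <- function(d) {
    sel <- keep & region == "track" & dir == d
    occ <- bin_counts(df$x[sel], track_edges) * dt
    ssel <- spike_keep & region[si] == "track" & dir[si] == d
    cnt <- bin_counts(df$x[si][ssel], track_edges)
    valid <- occ >= occ_min * bin_track * env$track_width
    raw <- ifelse(occ > 0, cnt / occ, NA_real_)
    rate <- smooth_masked_1d(cnt, valid, sigma_track / bin_track) /
      pmax(smooth_masked_1d(occ, valid, sigma_track / bin_track), 1e-12)
    rate[!valid] <- NA_real_
    list(centers = centers, rate = rate, raw = raw, occupancy = occ,
         valid = valid, count = cnt)
  }
  mk_box <- function(side) {
    xr <- if (side == "left") c(-env$endbox_depth, 0)
          else c(env$track_length, env$track_length + env$endbox_depth)
    xe <- seq(xr[1], xr[2], by = bin_box)
    ye <- seq(-env$endbox_width / 2, env$endbox_width / 2, by = bin_box)
    sel <- keep & region == paste0("box_", side)
    bx <- cut(df$x[sel], xe, labels = FALSE, include.lowest = TRUE)
    by <- cut(df$y[sel], ye, labels = FALSE, include.lowest = TRUE)
    occ <- matrix(0, length(xe) - 1L, length(ye) - 1L)
    ok <- !is.na(bx) & !is.na(by)
    if (any(ok)) {
      tb <- table(factor(bx[ok], levels = seq_len(nrow(occ))),
                  factor(by[ok], levels = seq_len(ncol(occ))))
      occ <- occ + as.matrix(tb) * dt
    }
    ssel <- spike_keep & region[si] == paste0("box_", side)
    sxi <- cut(df$x[si][ssel], xe, labels = FALSE, include.lowest = TRUE)
    syi <- cut(df$y[si][ssel], ye, labels = FALSE, include.lowest = TRUE)
    cnt <- matrix(0, nrow(occ), ncol(occ))
    ok <- !is.na(sxi) & !is.na(syi)
    if (any(ok)) {
      tb <- table(factor(sxi[ok], levels = seq_len(nrow(cnt))),
                  factor(syi[ok], levels = seq_len(ncol(cnt))))
      cnt <- cnt + as.matrix(tb)
    }
    valid <- occ >= occ_min * bin_box^2
    raw <- ifelse(occ > 0, cnt / occ, NA_real_)
    rate <- smooth_masked_2d(cnt, valid, sigma_box / bin_box) /
      pmax(smooth_masked_2d(occ, valid, sigma_box / bin_box), 1e-12)
    rate[!valid] <- NA_real_
    list(x = (xe[-1] + xe[-length(xe)]) / 2, y = (ye[-1] + ye[-length(ye)]) / 2,
         rate = rate, raw = raw, occupancy = occ, valid = valid, count = cnt,
         bin = bin_box)
  }
  structure(list(track = list(leftward = mk_track("leftward"),
                              rightward = mk_track("rightward")),
                 box = list(left = mk_box("left"), right = mk_box("right")),
                 env = env, spike_count_used = used,
                 params = list(bin_track = bin_track, bin_box = bin_box,
                               sigma_track = sigma_track, sigma_box = sigma_box,
                               v_thresh = v_thresh, cs_exclusion = cs_exclusion,
                               occ_min = occ_min)),
            class = "eb_ratemap")
}

#' @export
print.eb_ratemap <- function(x, ...) {
  pk <- suppressWarnings(max(c(x$track$leftward$rate, x$track$rightward$rate,
                               x$box$left$rate, x$box$right$rate), na.rm = TRUE))
  cat(sprintf("<eb_ratemap> peak %.2f Hz; %d spikes used\n",
              if (is.finite(pk)) pk else NA_real_, x$spike_count_used))
  invisible(x)
}

#' @export
plot.eb_ratemap <- function(x, ...) {
  graphics::plot(x$track$rightward$centers, x$track$rightward$rate, type = "l",
                 col = "tomato3", xlab = "track position (cm)",
                 ylab = "rate (Hz)", ...)
  graphics::lines(x$track$leftward$centers, x$track$leftward$rate,
                  col = "steelblue")
  graphics::legend("topright", c("rightward", "leftward"), lty = 1,
                   col = c("tomato3", "steelblue"), bty = "n")
}

# Largest 4-connected suprathreshold component of a matrix (valid bins only).
largest_component_2d <- function(above) {
  above[is.na(above)] <- FALSE
  lab <- matrix(0L, nrow(above), ncol(above))
  cur <- 0L
  best <- 0L
  for (i in seq_len(nrow(above))) for (j in seq_len(ncol(above))) {
    if (above[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i, j))
      size <- 0L
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        if (p[1] < 1 || p[2] < 1 || p[1] > nrow(above) || p[2] > ncol(above))
          next
        if (!above[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
        lab[p[1], p[2]] <- cur
        size <- size + 1L
        stack <- c(stack, list(p + c(1, 0)), list(p - c(1, 0)),
                   list(p + c(0, 1)), list(p - c(0, 1)))
      }
      best <- max(best, size)
    }
  }
  best
}

#' Classify a cell's spatial tuning
#'
#' A region holds a place field when it contains a contiguous run of at
#' least `min_bins` valid bins above `peak_thresh` (2 Hz). Classes:
#' `no_field`, `endbox_only`, `track_only`, `track_and_endbox`.
#'
#' @param map an `eb_ratemap`
#' @param peak_thresh field peak threshold in Hz
#' @param min_bins minimum contiguous suprathreshold bins
#' @return list with `class`, `peak` (Hz), and logicals `track_field`,
#'   `box_field`
#' @export
classify_spatial <- function(map, peak_thresh = 2, min_bins = 3L) {
  run_len <- function(x) {
    x[is.na(x)] <- FALSE
    r <- rle(x)
    m <- r$lengths[r$values]
    if (length(m)) max(m) else 0L
  }
  track_field <- any(vapply(map$track, function(m)
    run_len(m$rate > peak_thresh & m$valid) >= min_bins, logical(1)))
  box_field <- any(vapply(map$box, function(m)
    largest_component_2d(m$rate > peak_thresh & m$valid) >= min_bins,
    logical(1)))
  peak <- suppressWarnings(max(c(map$track$leftward$rate,
                                 map$track$rightward$rate,
                                 map$box$left$rate, map$box$right$rate),
                               na.rm = TRUE))
  cls <- if (track_field && box_field) "track_and_endbox"
         else if (track_field) "track_only"
         else if (box_field) "endbox_only"
         else "no_field"
  list(class = cls, peak = if (is.finite(peak)) peak else 0,
       track_field = track_field, box_field = box_field)
}

# Map value at positions (x, y) with direction labels ("leftward",
# "rightward", or NA => mean of the two directional track maps). NA where the
# bin is invalid or outside the mapped area.
ratemap_lookup <- function(map, x, y, dir) {
  env <- map$env
  region <- position_region(env, x, y)
  out <- rep(NA_real_, length(x))
  tl <- map$track$leftward; tr <- map$track$rightward
  bw <- tl$centers[2] - tl$centers[1]
  on_t <- region == "track"
  if (any(on_t)) {
    bi <- pmin(length(tl$centers), pmax(1L, floor(x[on_t] / bw) + 1L))
    vl <- tl$rate[bi]; vr <- tr$rate[bi]
    d <- dir[on_t]
    v <- ifelse(!is.na(d) & d == "leftward", vl,
                ifelse(!is.na(d) & d == "rightward", vr,
                       (ifelse(is.na(vl), 0, vl) + ifelse(is.na(vr), 0, vr)) /
                         ((!is.na(vl)) + (!is.na(vr)))))
    v[is.na(vl) & is.na(vr)] <- NA_real_
    out[on_t] <- v
  }
  for (side in c("left", "right")) {
    bm <- map$box[[side]]
    inb <- region == paste0("box_", side)
    if (!any(inb)) next
    bi <- pmin(length(bm$x), pmax(1L, floor((x[inb] - (bm$x[1] - bm$bin / 2)) / bm$bin) + 1L))
    bj <- pmin(length(bm$y), pmax(1L, floor((y[inb] - (bm$y[1] - bm$bin / 2)) / bm$bin) + 1L))
    out[inb] <- bm$rate[cbind(bi, bj)]
  }
  out
}

#' Place-field intensity over a trial window
#'
#' Time average of the rate map along the animal's trajectory over
#' `[t1, t2]`, using the direction-appropriate track map while on the track
#' and the endbox map while in an endbox. Samples landing on invalid bins
#' are excluded from the average; returns `NA` when every sample is invalid.
#'
#' @param map an `eb_ratemap`
#' @param traj an `eb_trajectory`
#' @param t1,t2 averaging window in seconds (`t2 > t1`)
#' @param v_thresh speed below which the sample counts as stationary (its
#'   track-map direction is then the mean over directions)
#' @param speed optional precomputed per-sample speed (from
#'   [estimate_speed()]), avoiding recomputation over many windows
#' @return intensity in Hz, or `NA`
#' @export
place_field_intensity <- function(map, traj, t1, t2, v_thresh = 2,
                                  speed = NULL) {
  if (t2 <= t1) stop("t2 must exceed t1")
  df <- traj$traj
  if (t1 < min(df$t) || t2 > max(df$t) + 1 / traj$fs)
    stop("window outside the trajectory span")
  sel <- which(df$t >= t1 & df$t <= t2)
  if (!length(sel)) sel <- which.min(abs(df$t - (t1 + t2) / 2))
  if (is.null(speed)) speed <- estimate_speed(traj)
  sp <- speed[sel]
  n <- nrow(df)
  vx <- (df$x[pmin(n, sel + 1L)] - df$x[pmax(1L, sel - 1L)]) /
    (df$t[pmin(n, sel + 1L)] - df$t[pmax(1L, sel - 1L)])
  dir <- ifelse(sp <= v_thresh, NA_character_,
                ifelse(vx > 0, "rightward", "leftward"))
  v <- ratemap_lookup(map, df$x[sel], df$y[sel], dir)
  if (all(is.na(v))) return(NA_real_)
  mean(v, na.rm = TRUE)
}

#' Per-trial place-field intensity
#'
#' Applies [place_field_intensity()] to the post-CS analysis window of each
#' trial (CS onset to US onset, i.e. 500 ms).
#'
#' @param map an `eb_ratemap`
#' @param traj an `eb_trajectory`
#' @param trials trial table
#' @param window `c(start, end)` offsets from CS onset in seconds
#' @return numeric vector of intensities (Hz) per trial, `NA` where undefined
#' @export
trial_intensity <- function(map, traj, trials, window = c(0, 0.5)) {
  sp <- estimate_speed(traj)
  vapply(seq_len(nrow(trials)), function(k)
    tryCatch(place_field_intensity(map, traj,
                                   trials$cs_onset[k] + window[1],
                                   trials$cs_onset[k] + window[2],
                                   speed = sp),
             error = function(e) NA_real_),
    numeric(1))
}

#' Putative pyramidal-cell classification
#'
#' A unit is a putative pyramidal cell when its mean firing rate is below
#' 4 Hz, its spike width above 0.25 ms, and more than 5% of its inter-spike
#' intervals are shorter than 10 ms (all inequalities strict).
#'
#' @param mean_rate mean firing rate in Hz
#' @param spike_width spike width in ms
#' @param burst_fraction fraction of ISIs < 10 ms
#' @return `TRUE`/`FALSE`, or `NA` when any feature is missing
#' @export
classify_pyramidal <- function(mean_rate, spike_width, burst_fraction) {
  if (any(is.na(c(mean_rate, spike_width, burst_fraction)))) return(NA)
  mean_rate < 4 && spike_width > 0.25 && burst_fraction > 0.05
}
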