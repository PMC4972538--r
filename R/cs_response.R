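# Stimulus-evoked firing statistics: pre/post window counts, the Poisson
# trial-reliability statistic (observed vs expected), the heuristic
# signed-rank test, the spatial-tuning correlation, peri-event rate traces
# and predicted-vs-observed rate comparisons.

#' Spike counts in trial-aligned windows
#'
#' Counts spikes in a 500 ms window per trial: `pre_cs` is the 500 ms
#' immediately before CS onset, `post_cs` the 500 ms immediately after (i.e.
#' up to US onset), `post_us` the 500 ms following US offset. Spikes inside
#' the 10 ms US delivery window never contribute (electrical artifacts
#' preclude spike detection there), which matters only for `custom` windows
#' spanning it.
#'
#' @param spikes numeric vector of spike times in s
#' @param trials trial table
#' @param window one of `"pre_cs"`, `"post_cs"`, `"post_us"`, or a numeric
#'   `c(start, end)` offset from CS onset in s for a custom window
#' @return integer vector of counts, one per trial
#' @export
window_counts <- function(spikes, trials, window = "post_cs") {
  if (is.character(window)) {
    window <- match.arg(window, c("pre_cs", "post_cs", "post_us"))
    off <- switch(window,
                  pre_cs = c(-0.5, 0),
                  post_cs = c(0, 0.5),
                  post_us = NULL)
  } else {
    stopifnot(is.numeric(window), length(window) == 2L)
    off <- window
    window <- "custom"
  }
  n <- nrow(trials)
  out <- integer(n)
  for (k in seq_len(n)) {
    if (identical(window, "post_us")) {
      a <- trials$us_onset[k] + trials$us_duration[k]
      b <- a + 0.5
    } else {
      a <- trials$cs_onset[k] + off[1]
      b <- trials$cs_onset[k] + off[2]
    }
    inw <- spikes >= a & spikes < b
    # exclude the US artifact window
    inw <- inw & !(spikes >= trials$us_onset[k] &
                     spikes < trials$us_onset[k] + trials$us_duration[k])
    out[k] <- sum(inw)
  }
  out
}

#' Expected Poisson response reliability
#'
#' Probability that an independent Poisson post-count exceeds (direction
#' `"increase"`) or falls below (`"decrease"`) the pre-count, given the
#' cell's trial-averaged expected counts: `P(k2 > k1) = sum_k1 f(k1; l1) *
#' P(k2 > k1; l2)`. The sum over `k1` is truncated at the `1 - 1e-13`
#' Poisson quantile so the neglected tail is below 1e-12.
#'
#' @param lambda1 expected pre-CS spike count per trial (>= 0)
#' @param lambda2 expected post-CS spike count per trial (>= 0)
#' @param direction `"increase"` for `P(k2 > k1)`, `"decrease"` for
#'   `P(k2 < k1)`
#' @return probability in `[0, 1]`
#' @examples
#' expected_reliability(0, log(2))   # 1 - exp(-log(2)) = 0.5
#' @export
expected_reliability <- function(lambda1, lambda2,
                                 direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  if (!is.finite(lambda1) || !is.finite(lambda2) || lambda1 < 0 || lambda2 < 0)
    stop("lambda1 and lambda2 must be finite and non-negative")
  if (direction == "decrease") return(expected_reliability(lambda2, lambda1))
  kmax <- stats::qpois(1 - 1e-13, lambda1)
  k1 <- 0:kmax
  sum(stats::dpois(k1, lambda1) * stats::ppois(k1, lambda2, lower.tail = FALSE))
}

#' Observed response reliability
#'
#' Fraction of trials in which the post-CS count strictly exceeds
#' (`"increase"`) or falls below (`"decrease"`) the pre-CS count. Ties never
#' count.
#'
#' @param pre_counts,post_counts equal-length integer vectors
#' @param direction see [expected_reliability()]
#' @return fraction in `[0, 1]`
#' @export
observed_reliability <- function(pre_counts, post_counts,
                                 direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  if (length(pre_counts) != length(post_counts) || length(pre_counts) < 1L)
    stop("pre and post counts must be equal-length, non-empty vectors")
  if (direction == "increase") mean(post_counts > pre_counts)
  else mean(post_counts < pre_counts)
}

#' Heuristic signed-rank test of the pre/post rate change
#'
#' Two-sided Wilcoxon signed-rank test on per-trial pre- vs post-CS counts
#' (exact for small tie-free samples, normal approximation with tie
#' correction otherwise). The result carries a `heuristic` flag: spatial
#' tuning and brain state violate the i.i.d. assumption, so the p-value is a
#' descriptive screen, not calibrated inference. All-tied input returns
#' p = 1 with a flag.
#'
#' @param pre_counts,post_counts equal-length count vectors
#' @return list with `p`, `direction` (`increase`/`decrease`/`none`),
#'   `all_tied`, `heuristic = TRUE`
#' @export
signed_rank_change <- function(pre_counts, post_counts, exact_max_n = 20L) {
  stopifnot(length(pre_counts) == length(post_counts))
  d <- post_counts - pre_counts
  if (all(d == 0))
    return(list(p = 1, direction = "none", all_tied = TRUE, heuristic = TRUE))
  dz <- d[d != 0]
  p <- if (length(dz) <= exact_max_n)
    signed_rank_exact_p(dz)
  else suppressWarnings(
    stats::wilcox.test(post_counts, pre_counts, paired = TRUE)$p.value)
  dirn <- if (sum(d > 0) == sum(d < 0)) {
    if (mean(d) > 0) "increase" else if (mean(d) < 0) "decrease" else "none"
  } else if (sum(d > 0) > sum(d < 0)) "increase" else "decrease"
  list(p = p, direction = dirn, all_tied = FALSE, heuristic = TRUE)
}

# Exact two-sided signed-rank p under the sign-flip null, valid with tied
# ranks: dynamic programming over the distribution of V = sum of positive
# ranks (average ranks doubled to stay integral).
signed_rank_exact_p <- function(d) {
  r2 <- round(2 * rank(abs(d)))
  v_obs <- sum(r2[d > 0])
  dist <- c(1, rep(0, sum(r2)))        # dist[v + 1] = #assignments with V = v
  for (r in r2) {
    shifted <- c(rep(0, r), dist[seq_len(length(dist) - r)])
    dist <- dist + shifted
  }
  dist <- dist / sum(dist)
  lo <- sum(dist[seq_len(v_obs + 1L)])
  hi <- sum(dist[(v_obs + 1L):length(dist)])
  min(1, 2 * min(lo, hi))
}

#' Spatial-tuning correlation of the CS response
#'
#' Spearman rank correlation between per-trial CS-evoked spike counts and
#' the place-field intensity at the delivery locations (average-rank tie
#' handling). Cells that never fired any spikes following the CS are
#' assigned a correlation of zero.
#'
#' @param post_counts per-trial post-CS spike counts
#' @param intensity per-trial place-field intensity (`NA` allowed; those
#'   trials are dropped)
#' @return Spearman's rho in `[-1, 1]` (0 for silent cells), or `NA` when
#'   intensity is undefined on all trials
#' @export
tuning_correlation <- function(post_counts, intensity) {
  ok <- is.finite(intensity)
  if (!any(ok)) return(NA_real_)
  post <- post_counts[ok]
  ii <- intensity[ok]
  if (sum(post) == 0) return(0)
  if (length(post) < 5L)
    warning("fewer than 5 trials with defined intensity; rho is unstable")
  if (stats::sd(ii) == 0 || stats::sd(post) == 0) return(0)
  suppressWarnings(stats::cor(post, ii, method = "spearman"))
}

#' Per-cell CS-response summary
#'
#' Bundles the window counts, mean rates, signed-rank p, observed and
#' expected reliability (in the direction of the mean change) and the
#' tuning correlation for one cell.
#'
#' @param spikes spike-time vector
#' @param trials trial table
#' @param intensity per-trial place-field intensity (optional)
#' @return `eb_cs_summary` list
#' @export
cs_response_summary <- function(spikes, trials, intensity = NULL) {
  pre <- window_counts(spikes, trials, "pre_cs")
  post <- window_counts(spikes, trials, "post_cs")
  sr <- signed_rank_change(pre, post)
  dirn <- if (sr$direction == "decrease") "decrease" else "increase"
  l1 <- mean(pre)
  l2 <- mean(post)
  structure(list(pre_counts = pre, post_counts = post,
                 pre_rate = l1 / 0.5, post_rate = l2 / 0.5,
                 lambda1 = l1, lambda2 = l2,
                 p_signed_rank = sr$p, direction = sr$direction,
                 observed_reliability = observed_reliability(pre, post, dirn),
                 expected_reliability = expected_reliability(l1, l2, dirn),
                 rho = if (is.null(intensity)) NA_real_
                       else tuning_correlation(post, intensity),
                 n_trials = nrow(trials), heuristic = TRUE),
            class = "eb_cs_summary")
}

#' @export
print.eb_cs_summary <- function(x, ...) {
  cat(sprintf(
    "<eb_cs_summary> %d trials: %.2f -> %.2f Hz (%s, p=%.3g, heuristic)\n  reliability observed %.2f vs expected %.2f; rho = %s\n",
    x$n_trials, x$pre_rate, x$post_rate, x$direction, x$p_signed_rank,
    x$observed_reliability, x$expected_reliability,
    ifelse(is.na(x$rho), "NA", sprintf("%.2f", x$rho))))
  invisible(x)
}

#' Peri-event firing-rate traces and rasters
#'
#' Trial-averaged firing rate in bins relative to CS onset, optionally split
#' by a per-trial grouping (state, in/out of field, intensity stratum,
#' ripple presence), plus a raster (per-trial relative spike times) that can
#' be ordered chronologically, by intensity, or by a supplied key such as
#' ripple time.
#'
#' @param spikes spike-time vector
#' @param trials trial table
#' @param t_range window around CS onset in s
#' @param binwidth bin width in s (default 0.02)
#' @param group optional factor/character per trial; empty groups are omitted
#' @param order_by `"chronological"`, `"intensity"`, or a numeric key
#' @param intensity per-trial intensity (needed for `order_by = "intensity"`)
#' @return `eb_peri`: `bin_centers` (s), per-group rate traces (Hz) with
#'   trial counts, and the ordered raster (list of spike-time vectors)
#' @export
peri_event_rates <- function(spikes, trials, t_range = c(-1, 1.5),
                             binwidth = 0.02, group = NULL,
                             order_by = "chronological", intensity = NULL) {
  n <- nrow(trials)
  rel <- lapply(seq_len(n), function(k) {
    s <- spikes - trials$cs_onset[k]
    s[s >= t_range[1] & s < t_range[2]]
  })
  edges <- seq(t_range[1], t_range[2], by = binwidth)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  if (is.null(group)) group <- rep("all", n)
  groups <- unique(as.character(group))
  traces <- list()
  for (g in groups) {
    sel <- which(as.character(group) == g)
    if (!length(sel)) next
    cnt <- bin_counts(unlist(rel[sel]), edges)
    traces[[g]] <- list(rate = cnt / (length(sel) * binwidth), n_trials = length(sel))
  }
  ord <- if (identical(order_by, "chronological")) order(trials$cs_onset)
         else if (identical(order_by, "intensity")) {
           if (is.null(intensity)) stop("intensity required for this ordering")
           order(intensity)
         } else order(order_by)
  structure(list(bin_centers = centers, traces = traces,
                 raster = rel[ord], order = ord, binwidth = binwidth),
            class = "eb_peri")
}

#' @export
plot.eb_peri <- function(x, ...) {
  cols <- grDevices::hcl.colors(max(2L, length(x$traces)), "Dark 2")
  ylim <- range(unlist(lapply(x$traces, `[[`, "rate")))
  graphics::plot(NA, xlim = range(x$bin_centers), ylim = ylim,
                 xlab = "time from CS onset (s)", ylab = "rate (Hz)", ...)
  for (i in seq_along(x$traces))
    graphics::lines(x$bin_centers, x$traces[[i]]$rate, col = cols[i])
  graphics::legend("topright", names(x$traces), lty = 1,
                   col = cols[seq_along(x$traces)], bty = "n")
  graphics::abline(v = 0, lty = 3)
}

#' Predicted vs observed stimulus-evoked rates
#'
#' Stratifies trials by place-field intensity into logarithmic bins (with a
#' dedicated zero/near-zero stratum), and per stratum reports the predicted
#' rate (mean intensity), the observed mean rate with a percentile bootstrap
#' confidence interval over trials, and a discrepancy score
#' `mean |log((obs + eps) / (pred + eps))|` across strata.
#'
#' @param counts per-trial spike counts in the analysis window
#' @param intensity per-trial place-field intensity in Hz
#' @param window_length analysis window length in s (counts / length = rate)
#' @param n_boot bootstrap resamples (default 2000)
#' @param eps floor for the log-ratio, Hz (default 0.01, the display floor)
#' @param n_strata number of logarithmic intensity strata
#' @param conf confidence level
#' @param seed RNG seed for the bootstrap
#' @return data.frame per stratum (`intensity_lo, intensity_hi, predicted,
#'   observed, ci_lo, ci_hi, n`), with the discrepancy score as attribute
#'   `"discrepancy"`
#' @export
predicted_vs_observed <- function(counts, intensity, window_length = 0.5,
                                  n_boot = 2000, eps = 0.01, n_strata = 6,
                                  conf = 0.95, seed = 1L) {
  ok <- is.finite(intensity)
  counts <- counts[ok]; intensity <- intensity[ok]
  if (!length(counts)) stop("no trials with defined intensity")
  lo_cut <- eps
  pos <- intensity > lo_cut
  edges <- if (any(pos))
    exp(seq(log(lo_cut), log(max(intensity[pos]) + 1e-9),
            length.out = n_strata)) else lo_cut
  stratum <- findInterval(intensity, edges, rightmost.closed = TRUE)
  rows <- list()
  with_seed(seed, {
    for (s in sort(unique(stratum))) {
      sel <- which(stratum == s)
      rate <- counts[sel] / window_length
      bm <- if (length(sel) > 1L)
        replicate(n_boot, mean(rate[sample.int(length(sel), replace = TRUE)]))
        else rate
      ci <- stats::quantile(bm, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                            names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        intensity_lo = if (s == 0) 0 else edges[s],
        intensity_hi = if (s >= length(edges)) max(intensity) else edges[s + 1L],
        predicted = mean(intensity[sel]),
        observed = mean(rate), ci_lo = ci[1], ci_hi = ci[2],
        n = length(sel))
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "discrepancy") <-
    mean(abs(log((out$observed + eps) / (out$predicted + eps))))
  out
}
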