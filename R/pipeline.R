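# End-to-end orchestration: session directory I/O, staged analysis with a
# manifest, and figure-level summary reports.

#' Write a session to a directory of plain tables
#'
#' Layout: `trajectory.csv` (t, x, y), `trials.csv`, `cells.csv`,
#' `spikes.csv` (cell, t), `emg.f32` + `emg.json`, `lfp.f32` (float32,
#' channel-interleaved) + `lfp.json` (sample rate, channel count), and
#' `ground_truth.json`.
#'
#' @param session an `eb_session`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  utils::write.csv(session$traj$traj, p("trajectory.csv"), row.names = FALSE)
  utils::write.csv(session$trials, p("trials.csv"), row.names = FALSE)
  utils::write.csv(session$cells, p("cells.csv"), row.names = FALSE)
  sp <- data.frame(cell = rep(seq_along(session$spk$spikes),
                              lengths(session$spk$spikes)),
                   t = unlist(session$spk$spikes))
  utils::write.csv(sp, p("spikes.csv"), row.names = FALSE)
  if (!is.null(session$lfp)) {
    m <- session$lfp$lfp$samples
    con <- file(p("lfp.f32"), "wb")
    writeBin(as.numeric(t(m)), con, size = 4L)
    close(con)
    jsonlite::write_json(list(fs = session$lfp$lfp$fs, n_channels = ncol(m),
                              t0 = session$lfp$lfp$t0, dtype = "float32",
                              order = "channel-interleaved"),
                         p("lfp.json"), auto_unbox = TRUE)
  }
  if (!is.null(session$emg)) {
    con <- file(p("emg.f32"), "wb")
    writeBin(as.numeric(session$emg$emg$samples), con, size = 4L)
    close(con)
    jsonlite::write_json(list(fs = session$emg$emg$fs,
                              t0 = session$emg$emg$t0, dtype = "float32"),
                         p("emg.json"), auto_unbox = TRUE)
  }
  gt <- list(model = session$model, seed = session$seed,
             micro_state = session$traj$micro_state,
             ripples = session$spk$ripples,
             arousal_windows = session$spk$arousal_windows,
             blinks = if (is.null(session$emg)) NULL else session$emg$blinks)
  jsonlite::write_json(gt, p("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' Read a session directory written by [write_session()]
#'
#' @param dir session directory
#' @return an `eb_session` (ground-truth fields restored where present)
#' @export
read_session <- function(dir) {
  p <- function(f) file.path(dir, f)
  traj_df <- utils::read.csv(p("trajectory.csv"))
  trials <- utils::read.csv(p("trials.csv"))
  cells <- utils::read.csv(p("cells.csv"))
  gt <- jsonlite::read_json(p("ground_truth.json"), simplifyVector = TRUE)
  fs <- round(1 / stats::median(diff(traj_df$t)))
  traj <- structure(list(traj = traj_df, micro_state = gt$micro_state,
                         env = eb_env(), fs = fs, params = list()),
                    class = "eb_trajectory")
  sp <- utils::read.csv(p("spikes.csv"))
  spikes <- lapply(seq_len(nrow(cells)), function(i) sort(sp$t[sp$cell == i]))
  spk <- structure(list(spikes = spikes, cells = cells,
                        ripples = gt$ripples, model = gt$model,
                        arousal_windows = gt$arousal_windows, params = list()),
                   class = "eb_spikes")
  lfp <- NULL
  if (file.exists(p("lfp.json"))) {
    hdr <- jsonlite::read_json(p("lfp.json"), simplifyVector = TRUE)
    con <- file(p("lfp.f32"), "rb")
    raw <- readBin(con, "numeric", n = file.info(p("lfp.f32"))$size / 4L,
                   size = 4L)
    close(con)
    m <- matrix(raw, ncol = hdr$n_channels, byrow = TRUE)
    lfp <- structure(list(lfp = eb_timeseries(m, hdr$fs, hdr$t0),
                          ripples = gt$ripples, params = list()),
                     class = "eb_lfp")
  }
  emg <- NULL
  if (file.exists(p("emg.json"))) {
    hdr <- jsonlite::read_json(p("emg.json"), simplifyVector = TRUE)
    con <- file(p("emg.f32"), "rb")
    raw <- readBin(con, "numeric", n = file.info(p("emg.f32"))$size / 4L,
                   size = 4L)
    close(con)
    emg <- structure(list(emg = eb_timeseries(raw, hdr$fs, hdr$t0),
                          blinks = gt$blinks, params = list()),
                     class = "eb_emg")
  }
  structure(list(traj = traj, trials = trials, cells = cells, spk = spk,
                 lfp = lfp, emg = emg, model = gt$model, seed = gt$seed),
            class = "eb_session")
}

# Content hash of an R object (stable across runs for identical objects).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, compress = FALSE, version = 2L)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline on a session
#'
#' Executes the stages in dependency order — behaviour (CR detection, trial
#' states), place fields (rate maps, spatial classes, per-trial intensity),
#' CS response (per-cell summaries), ripples (detection, peri-CS rates,
#' ripple/no-ripple split), theta (run-trial phase transition, LFP-state
#' classification) — recording per-stage status in a manifest. Stages whose
#' inputs are missing are skipped with an explicit status; completed stages
#' keep their outputs.
#'
#' @param session an `eb_session` (or a directory path readable by
#'   [read_session()])
#' @param theta_channel LFP channel used for theta analysis
#' @param n_cells_max optionally restrict the number of analysed cells
#' @return `eb_analysis`: list of stage outputs (`behavior`, `states`,
#'   `maps`, `spatial`, `intensity`, `cs`, `ripples`, `theta`) plus
#'   `manifest` (per-stage status and content hashes, config echo, seed)
#' @export
run_session_analysis <- function(session, theta_channel = 1L,
                                 n_cells_max = Inf) {
  if (is.character(session)) session <- read_session(session)
  stopifnot(inherits(session, "eb_session"))
  status <- list()
  out <- list()
  # behaviour
  out$states <- classify_trial_state(session$traj, session$trials)
  if (!is.null(session$emg)) {
    out$behavior <- detect_crs(session$emg, session$trials)
    status$behavior <- "complete"
  } else {
    status$behavior <- "skipped: no EMG"
  }
  status$states <- "complete"
  # place fields and CS response per cell
  nc <- min(length(session$spk$spikes), n_cells_max)
  out$maps <- vector("list", nc)
  out$spatial <- vector("list", nc)
  out$intensity <- matrix(NA_real_, nc, nrow(session$trials))
  out$cs <- vector("list", nc)
  for (i in seq_len(nc)) {
    m <- build_rate_map(session$spk$spikes[[i]], session$traj, session$trials)
    out$maps[[i]] <- m
    out$spatial[[i]] <- classify_spatial(m)
    out$intensity[i, ] <- trial_intensity(m, session$traj, session$trials)
    out$cs[[i]] <- cs_response_summary(session$spk$spikes[[i]],
                                       session$trials, out$intensity[i, ])
  }
  status$place_fields <- "complete"
  status$cs_response <- "complete"
  # ripples + theta need the LFP
  if (!is.null(session$lfp)) {
    quiet_mask <- NULL
    det <- detect_ripples(session$lfp)
    out$ripples <- list(
      events = det,
      rate = ripple_rate(det, session$trials, out$states),
      split = split_trials_by_ripple(det, session$trials))
    status$ripples <- "complete"
    ch <- ts_channel(session$lfp$lfp, theta_channel)
    run_trials <- session$trials[out$states == "run", , drop = FALSE]
    out$theta <- list(
      lfp_state = classify_trial_lfp_state(ch, session$trials, out$states),
      transition = if (nrow(run_trials) >= 5L)
        phase_transition(ch, run_trials, "CS") else NULL)
    status$theta <- if (nrow(run_trials) >= 5L) "complete"
                    else "skipped: fewer than 5 run trials"
  } else {
    status$ripples <- "skipped: no LFP"
    status$theta <- "skipped: no LFP"
  }
  manifest <- list(
    seed = session$seed, model = session$model,
    n_cells = nc, n_trials = nrow(session$trials),
    status = status,
    hashes = list(states = object_hash(out$states),
                  intensity = object_hash(out$intensity),
                  cs = object_hash(out$cs),
                  ripples = if (!is.null(out$ripples))
                    object_hash(out$ripples$events$events) else NULL),
    version = as.character(utils::packageVersion("hippoblink")))
  structure(c(out, list(manifest = manifest)), class = "eb_analysis")
}

#' @export
print.eb_analysis <- function(x, ...) {
  cat("<eb_analysis>\n")
  for (s in names(x$manifest$status))
    cat(sprintf("  %-12s %s\n", s, x$manifest$status[[s]]))
  invisible(x)
}

#' Figure-level summary tables for an analysed session
#'
#' Machine-readable analogues of the headline panels: observed vs expected
#' reliability per cell, the tuning-correlation distribution, spatial-class
#' counts, state-split pre/post rates, peri-CS ripple rates by state, and
#' the theta phase-transition summary. Cells with no data yield explicit
#' `NA` rows rather than being dropped.
#'
#' @param an an `eb_analysis`
#' @return `eb_report`: named list of data.frames
#' @export
session_report <- function(an) {
  stopifnot(inherits(an, "eb_analysis"))
  cells <- data.frame(
    cell = seq_along(an$cs),
    pre_rate = vapply(an$cs, `[[`, numeric(1), "pre_rate"),
    post_rate = vapply(an$cs, `[[`, numeric(1), "post_rate"),
    p_signed_rank = vapply(an$cs, `[[`, numeric(1), "p_signed_rank"),
    observed_reliability = vapply(an$cs, `[[`, numeric(1),
                                  "observed_reliability"),
    expected_reliability = vapply(an$cs, `[[`, numeric(1),
                                  "expected_reliability"),
    rho = vapply(an$cs, `[[`, numeric(1), "rho"),
    total_post_spikes = vapply(an$cs, function(s) sum(s$post_counts),
                               numeric(1)),
    spatial_class = vapply(an$spatial, `[[`, character(1), "class"),
    peak_rate = vapply(an$spatial, `[[`, numeric(1), "peak"))
  spatial_counts <- as.data.frame(table(class = cells$spatial_class))
  states <- data.frame(state = c("run", "sit", "ambiguous"),
                       n = vapply(c("run", "sit", "ambiguous"),
                                  function(s) sum(an$states == s), numeric(1)))
  rip <- NULL
  if (!is.null(an$ripples)) {
    rip <- do.call(rbind, lapply(names(an$ripples$rate), function(s) {
      r <- an$ripples$rate[[s]]
      data.frame(state = s, rel_time = r$bin_centers, rate = r$rate,
                 n_trials = r$n_trials)
    }))
  }
  theta <- if (!is.null(an$theta) && !is.null(an$theta$transition))
    as.data.frame(an$theta$transition$summary) else NULL
  structure(list(cells = cells, spatial_counts = spatial_counts,
                 trial_states = states, ripple_rate = rip,
                 theta_transition = theta,
                 cr = if (!is.null(an$behavior))
                   data.frame(cr_rate = an$behavior$cr_rate,
                              ci_lo = an$behavior$cr_rate_ci[1],
                              ci_hi = an$behavior$cr_rate_ci[2]) else NULL),
            class = "eb_report")
}

#' @export
print.eb_report <- function(x, ...) {
  cat("<eb_report>\n")
  if (!is.null(x$cr))
    cat(sprintf("  CR rate: %.2f [%.2f, %.2f]\n", x$cr$cr_rate, x$cr$ci_lo,
                x$cr$ci_hi))
  cat(sprintf("  cells: %d; spatial classes: %s\n", nrow(x$cells),
              paste(sprintf("%s=%d", x$spatial_counts$class,
                            x$spatial_counts$Freq), collapse = ", ")))
  cat(sprintf("  trial states: %s\n",
              paste(sprintf("%s=%d", x$trial_states$state,
                            x$trial_states$n), collapse = ", ")))
  if (!is.null(x$theta_transition))
    cat(sprintf("  theta: circ cor %.2f, mean shift %.2f rad\n",
                x$theta_transition$circ_cor, x$theta_transition$mean_shift))
  invisible(x)
}

#' @export
plot.eb_report <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$cells$expected_reliability, x$cells$observed_reliability,
                 xlim = c(0, 1), ylim = c(0, 1), pch = 16, cex = 0.7,
                 xlab = "expected reliability", ylab = "observed reliability")
  graphics::abline(0, 1, lty = 3)
  graphics::hist(x$cells$rho, breaks = 20, main = "",
                 xlab = expression(rho ~ "(CS firing vs place-field intensity)"))
}
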