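#' Session design configuration
#'
#' Describes the target-acquisition session the generator emulates: seven
#' equidistant targets at 12.5-87.5% of workspace width, five analysis
#' blocks per modality (one trial per target per block, randomised order),
#' 60 Hz sampling, a 10 s trial window, and a fixed target half-width. The
#' defaults reproduce the study design: 7 targets x 5 blocks = 35 trials per
#' participant per modality.
#'
#' @param n_subjects Number of simulated participants.
#' @param modalities Character vector of modality labels.
#' @param target_distances Target centres in % workspace width.
#' @param n_blocks Analysis blocks per modality.
#' @param fs Sampling rate (Hz).
#' @param trial_window Trial duration (s).
#' @param target_halfwidth Half-width of the target band (% workspace
#'   width); default 3.6% — a 2.5 cm target radius on a 27-inch (68.6 cm)
#'   wide workspace.
#' @return An object of class `session_config`.
#' @export
session_config <- function(n_subjects = 10L,
                           modalities = c("manipulandum", "sonomyography"),
                           target_distances = c(12.5, 25, 37.5, 50,
                                                62.5, 75, 87.5),
                           n_blocks = 5L, fs = 60, trial_window = 10,
                           target_halfwidth = 3.6) {
  stopifnot(n_subjects >= 1L, length(modalities) >= 1L,
            all(target_distances > 0), all(target_distances <= 100),
            n_blocks >= 1L, fs > 0, trial_window > 0, target_halfwidth >= 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 modalities = modalities,
                 target_distances = target_distances,
                 n_blocks = as.integer(n_blocks),
                 fs = fs, trial_window = trial_window,
                 target_halfwidth = target_halfwidth),
            class = "session_config")
}

#' Trial-level noise model for the generator
#'
#' Parameterises how a simulated trial deviates from the ideal minimum-jerk
#' movement. The time to target for a movement of distance D (% width) is
#' drawn as `ttt_intercept + ttt_slope * D + Normal(0, ttt_jitter_sd)`
#' (floored at `min_ttt`); the full minimum-jerk duration is then derived by
#' inverting the 95%-of-target crossing fraction, so the generator's slope
#' parameter is directly the slope of measured time to target on distance.
#' The endpoint is the target centre plus truncated-Normal scatter bounded
#' by the target half-width. Zero-mean moving-average-filtered white noise,
#' rescaled to `trajectory_noise_sd` and shaped by a signal-dependent
#' envelope (the normalised minimum-jerk velocity bell: zero at both segment
#' ends, 1 at mid-movement), is added to the moving segment only, so the
#' rest and hold phases stay clean and onset detection stays meaningful.
#'
#' @param ttt_intercept,ttt_slope Time-to-target law: intercept (s) and
#'   slope (s per % distance, >= 0).
#' @param ttt_jitter_sd Trial-to-trial SD of the time to target (s).
#' @param trajectory_noise_sd SD of the additive trajectory noise (% width)
#'   at mid-movement.
#' @param noise_smoothing_window Moving-average width (samples) applied to
#'   the white noise before rescaling; sets the noise correlation time.
#' @param endpoint_sd SD of the endpoint scatter (% width), truncated at
#'   +/- the target half-width.
#' @param onset_delay_mean,onset_delay_sd Reaction-time delay before the
#'   movement starts (s); draws are floored at 0.
#' @param min_ttt Floor for the drawn time to target (s).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(ttt_intercept, ttt_slope, ttt_jitter_sd,
                        trajectory_noise_sd, noise_smoothing_window = 9L,
                        endpoint_sd = 0.5, onset_delay_mean = 0.15,
                        onset_delay_sd = 0.05, min_ttt = 0.2) {
  stopifnot(ttt_slope >= 0, ttt_jitter_sd >= 0, trajectory_noise_sd >= 0,
            endpoint_sd >= 0, onset_delay_sd >= 0, min_ttt > 0,
            noise_smoothing_window >= 1L)
  structure(list(ttt_intercept = ttt_intercept, ttt_slope = ttt_slope,
                 ttt_jitter_sd = ttt_jitter_sd,
                 trajectory_noise_sd = trajectory_noise_sd,
                 noise_smoothing_window = as.integer(noise_smoothing_window),
                 endpoint_sd = endpoint_sd,
                 onset_delay_mean = onset_delay_mean,
                 onset_delay_sd = onset_delay_sd,
                 min_ttt = min_ttt),
            class = "noise_model")
}

#' Default per-modality noise models
#'
#' Two presets emulating the study's reported regularities. The
#' manipulandum-like modality is slower but precise (trajectory noise SD
#' 1.5% width, anchored to the reported 0.53-2.36% trace-SD range) with time
#' to target rising 0.01 s per % distance from 0.45 s, giving a
#' longest-to-shortest time-to-target ratio near the reported 2.46x. The
#' sonomyography-like modality is faster but noisier (trajectory noise SD
#' 5%, anchored to the reported 4.27-5.82% range; larger trial-to-trial
#' jitter and endpoint scatter), with a shallower distance dependence
#' (ratio near the reported 1.83x) and hence higher peak velocities.
#'
#' @return Named list of [noise_model()] objects, one per default modality.
#' @export
noise_model_presets <- function() {
  list(
    manipulandum = noise_model(
      ttt_intercept = 0.45, ttt_slope = 0.01, ttt_jitter_sd = 0.08,
      trajectory_noise_sd = 1.5, noise_smoothing_window = 9L,
      endpoint_sd = 0.5, onset_delay_mean = 0.15, onset_delay_sd = 0.05),
    sonomyography = noise_model(
      ttt_intercept = 0.35, ttt_slope = 0.005, ttt_jitter_sd = 0.18,
      trajectory_noise_sd = 5, noise_smoothing_window = 9L,
      endpoint_sd = 1.2, onset_delay_mean = 0.20, onset_delay_sd = 0.08))
}

# Zero-mean truncated normal draw via rejection (bounds +/- bound).
rtruncnorm1 <- function(sd, bound) {
  if (sd == 0 || bound == 0) return(0)
  repeat {
    x <- stats::rnorm(1, 0, sd)
    if (abs(x) <= bound) return(x)
  }
}

# Signal-dependent noise envelope: the minimum-jerk velocity bell normalised
# to peak 1 (16 tau^2 (1-tau)^2). Motor noise grows with command magnitude,
# so the additive trajectory noise is scaled by the instantaneous speed of
# the ideal movement — zero at both segment ends (boundary conditions hold
# exactly), maximal at mid-movement (where the SD equals the nominal noise
# SD).
velocity_envelope <- function(n) {
  if (n == 1L) return(0)
  tau <- seq(0, 1, length.out = n)
  16 * tau^2 * (1 - tau)^2
}

#' Generate one synthetic trial
#'
#' Assembles a trial as: a flat pre-movement segment of length equal to the
#' reaction delay, a sampled minimum-jerk movement from 0 to the drawn
#' endpoint, and a hold at the endpoint until the end of the trial window.
#' Smoothed, tapered, zero-mean noise is added to the moving segment only.
#' Draws come from R's global RNG; seed via [set.seed()] or use
#' [generate_cohort()] which seeds once per cohort.
#'
#' @param distance Target centre (% workspace width).
#' @param noise A [noise_model()].
#' @param config A [session_config()].
#' @param subject_id,block,trial_id,modality Metadata for the emitted trial.
#' @return A list with `trial` (a [trial()] object) and `truth` (a one-row
#'   data frame with the generating values: true time to target, minimum-
#'   jerk duration, endpoint, onset delay).
#' @export
generate_trial <- function(distance, noise, config,
                           subject_id = "S01", block = 1L,
                           trial_id = "T001", modality = "synthetic") {
  stopifnot(inherits(noise, "noise_model"), inherits(config, "session_config"))
  ttt <- noise$ttt_intercept + noise$ttt_slope * distance +
    stats::rnorm(1, 0, noise$ttt_jitter_sd)
  if (ttt < noise$min_ttt) {
    warning("drawn time to target below floor; clamped to ", noise$min_ttt)
    ttt <- noise$min_ttt
  }
  xf <- distance + rtruncnorm1(noise$endpoint_sd, config$target_halfwidth)
  # invert the end rule: the 95%-of-target crossing happens at fraction
  # tau* of the full movement, so the MJT duration is ttt / tau*
  r <- 0.95 * distance / xf
  tau_star <- mjt_crossing_fraction(min(max(r, 0.05), 0.999))
  d <- ttt / tau_star
  delay <- max(stats::rnorm(1, noise$onset_delay_mean, noise$onset_delay_sd), 0)

  times <- seq(0, config$trial_window, by = 1 / config$fs)
  params <- mjt_params(x0 = 0, xf = xf, d = d, t_s = delay)
  x <- numeric(length(times))
  moving <- times >= delay & times <= delay + d
  x[moving] <- mjt_position(params, times[moving])
  x[times > delay + d] <- xf

  if (noise$trajectory_noise_sd > 0 && sum(moving) > 4L) {
    e <- moving_average(stats::rnorm(sum(moving)),
                        noise$noise_smoothing_window)
    s <- stats::sd(e)
    if (s > 0) {
      x[moving] <- x[moving] +
        e / s * noise$trajectory_noise_sd * velocity_envelope(sum(moving))
    }
  }

  list(trial = trial(subject_id, modality, block, trial_id, distance,
                     times, x),
       truth = data.frame(subject_id = subject_id, modality = modality,
                          block = block, trial_id = trial_id,
                          target_distance = distance,
                          true_time_to_target = ttt, true_duration = d,
                          true_endpoint = xf, true_onset_delay = delay))
}

#' Generate a synthetic cohort of trials
#'
#' For every subject x modality x block, one trial per target distance in
#' randomised order — the session design of the study (35 trials per
#' participant per modality under the defaults). A single RNG seed governs
#' every draw, so cohorts are bit-for-bit reproducible.
#'
#' @param config A [session_config()].
#' @param noise_models Named list of [noise_model()]s, one entry per
#'   modality in `config$modalities` (default: [noise_model_presets()]).
#' @param seed Integer RNG seed.
#' @return An object of class `cohort`: list with `trials` (list of
#'   [trial()] objects), `truth` (data frame of generating values),
#'   `config` and `seed`.
#' @export
generate_cohort <- function(config = session_config(),
                            noise_models = noise_model_presets(),
                            seed = 1L) {
  stopifnot(all(config$modalities %in% names(noise_models)))
  set.seed(as.integer(seed))
  trials <- list()
  truth <- list()
  k <- 0L
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("S%02d", s)
    for (mod in config$modalities) {
      nm <- noise_models[[mod]]
      for (b in seq_len(config$n_blocks)) {
        order_d <- sample(config$target_distances)
        for (dist in order_d) {
          k <- k + 1L
          g <- generate_trial(dist, nm, config,
                              subject_id = sid, block = b,
                              trial_id = sprintf("T%04d", k),
                              modality = mod)
          trials[[k]] <- g$trial
          truth[[k]] <- g$truth
        }
      }
    }
  }
  structure(list(trials = trials,
                 truth = do.call(rbind, truth),
                 config = config, seed = as.integer(seed)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d trials (%d subjects x %s, %d blocks, seed %d)\n",
    length(x$trials), x$config$n_subjects,
    paste(x$config$modalities, collapse = " + "), x$config$n_blocks, x$seed))
  invisible(x)
}

#' Estimate the additive trajectory-noise SD from trials at one distance
#'
#' Parameter-recovery estimator for the generator's `trajectory_noise_sd`.
#' For each trial the settled endpoint and detected onset fix the
#' minimum-jerk start and amplitude, the movement duration is fitted by
#' one-dimensional least squares, and the residuals of the trajectory from
#' that fitted minimum-jerk movement are collected over the movement.
#' Because the generator's noise is shaped by the normalised velocity-bell
#' envelope \eqn{16\tau^2(1-\tau)^2}, the noise SD is the residual RMS
#' divided by the envelope's RMS (\eqn{\sqrt{256 B(5,5)} \approx 0.637});
#' the per-trial estimates are combined as a root-mean-square.
#'
#' A finite-sample correction compensates for the variance the fitted
#' duration absorbs: the filtered noise has roughly `n / noise_window`
#' independent values per segment, of which the one fitted parameter
#' removes one, so the residual variance is inflated by
#' `n_eff / (n_eff - 1)`.
#'
#' @param trials Trials at a single target distance (cohort, list or table).
#' @param smooth_window Velocity smoothing for segmentation (samples).
#' @param noise_window The generator's noise moving-average width (samples),
#'   i.e. the correlation length of the additive noise.
#' @return Estimated noise SD in % workspace width.
#' @export
estimate_trajectory_noise_sd <- function(trials, smooth_window = 5L,
                                         noise_window = 9L) {
  tl <- as_trial_list(trials)
  dist <- unique(vapply(tl, `[[`, numeric(1), "target_distance"))
  if (length(dist) != 1L) {
    stop("noise-SD estimation expects trials at a single target distance")
  }
  env_rms <- sqrt(256 * beta(5, 5)) # RMS of 16 tau^2 (1-tau)^2 on [0, 1]
  est2 <- vapply(tl, function(tr) {
    v <- estimate_velocity(tr, smooth_window)
    onset <- detect_onset(v)
    if (is.na(onset)) return(NA_real_)
    settle <- tr$positions[length(tr$positions)]
    if (abs(settle) < 1e-9) return(NA_real_)
    t0 <- tr$times[onset]
    seg_t <- tr$times[tr$times >= t0] - t0
    seg_x <- tr$positions[tr$times >= t0]
    sse_d <- function(d) {
      tau <- pmin(seg_t / d, 1)
      sum((seg_x - settle * (10 * tau^3 - 15 * tau^4 + 6 * tau^5))^2)
    }
    t_max <- seg_t[length(seg_t)]
    d_hat <- stats::optimize(sse_d, c(0.05, min(3, t_max)))$minimum
    inside <- seg_t <= d_hat
    if (sum(inside) < 8L) return(NA_real_)
    tau <- seg_t[inside] / d_hat
    resid <- seg_x[inside] -
      settle * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
    n_eff <- max(sum(inside) / noise_window, 2)
    mean(resid^2) / env_rms^2 * n_eff / (n_eff - 1)
  }, numeric(1))
  est2 <- est2[is.finite(est2)]
  if (length(est2) < 10L) stop("too few usable trials to estimate noise SD")
  sqrt(mean(est2))
}

#' Flatten a cohort (or trial list) to the tidy long sample table
#'
#' One row per sample with the pipeline's CSV schema: `subject_id`,
#' `modality`, `block`, `trial_id`, `target_distance_pct`, `t_s`,
#' `position_pct`. The output round-trips through [read_trials()]
#' unchanged.
#'
#' @param x A `cohort` or list of [trial()] objects.
#' @return A data frame in the tidy long schema.
#' @export
trials_to_table <- function(x) {
  trials <- as_trial_list(x)
  do.call(rbind, lapply(trials, function(tr) {
    data.frame(subject_id = tr$subject_id, modality = tr$modality,
               block = tr$block, trial_id = tr$trial_id,
               target_distance_pct = tr$target_distance,
               t_s = tr$times, position_pct = tr$positions)
  }))
}
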