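#' Construct a single recorded trial
#'
#' One sampled cursor trajectory with its experimental metadata. Positions
#' are in percent of workspace width, normalised so that 0 is the start edge
#' and the movement is positive-going (see [read_trials()] for mirroring of
#' left-handed conventions). Times are in seconds, nominally uniform at the
#' acquisition rate `fs`.
#'
#' @param subject_id,trial_id Opaque labels.
#' @param modality Control modality label, e.g. `"manipulandum"` or
#'   `"sonomyography"`.
#' @param block Block number (integer >= 1).
#' @param target_distance Target centre in % workspace width, in (0, 100].
#' @param times Strictly increasing sample times (s), length >= 2.
#' @param positions Finite cursor positions (%), same length as `times`.
#' @return An object of class `trial`.
#' @export
trial <- function(subject_id, modality, block, trial_id,
                  target_distance, times, positions) {
  times <- as.numeric(times)
  positions <- as.numeric(positions)
  if (length(times) < 2L || length(times) != length(positions)) {
    stop("a trial needs at least 2 samples with matching times and positions")
  }
  if (any(diff(times) <= 0)) stop("sample times must be strictly increasing")
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (!is.finite(target_distance) || target_distance <= 0 ||
      target_distance > 100) {
    stop("target_distance must lie in (0, 100] % of workspace width")
  }
  structure(
    list(subject_id = as.character(subject_id),
         modality = as.character(modality),
         block = as.integer(block),
         trial_id = as.character(trial_id),
         target_distance = target_distance,
         times = times,
         positions = positions),
    class = "trial")
}

#' @export
print.trial <- function(x, ...) {
  cat(sprintf(
    "Trial %s (subject %s, %s, block %d): target %.4g%%, %d samples over %.3g s\n",
    x$trial_id, x$subject_id, x$modality, x$block, x$target_distance,
    length(x$times), x$times[length(x$times)] - x$times[1]))
  invisible(x)
}

# Median sampling rate of a trial (Hz).
trial_fs <- function(trial) 1 / stats::median(diff(trial$times))

#' Estimate movement velocity from sampled positions
#'
#' Backward first difference scaled by the per-interval sampling step
#' (`v[1] = 0`), followed by an optional centred moving average of odd width
#' `smooth_window`. Finite differencing at 60 Hz amplifies sensor noise, so
#' measured data is typically smoothed (the pipeline default is a 5-sample
#' window) while noise-free synthetic traces need none. Edges use a
#' shrinking window so the output length equals the input length.
#'
#' @param trial A [trial()] object.
#' @param smooth_window Odd positive integer; 1 disables smoothing.
#' @return Numeric velocity series (%/s), one value per sample.
#' @export
estimate_velocity <- function(trial, smooth_window = 1L) {
  stopifnot(inherits(trial, "trial"))
  if (smooth_window < 1L || smooth_window %% 2L != 1L) {
    stop("smooth_window must be an odd positive integer")
  }
  dt <- diff(trial$times)
  cv <- stats::sd(dt) / mean(dt)
  if (is.finite(cv) && cv > 0.01) {
    warning("non-uniform sampling (CV of dt = ", signif(cv, 2),
            "); using per-interval time steps")
  }
  v <- c(0, diff(trial$positions) / dt)
  moving_average(v, smooth_window)
}

# Centred moving average with shrinking windows at the edges.
moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  h <- (w - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect movement onset
#'
#' The task's rule: movement onset is the first sample where the movement
#' velocity is positive. `eps` and `debounce` generalise this for noisy
#' data: onset is the first index where `velocity > eps` holds for
#' `debounce` consecutive samples; the defaults (`eps = 0`, `debounce = 1`)
#' reproduce the literal rule.
#'
#' @param velocity Velocity series from [estimate_velocity()].
#' @param eps Velocity threshold (%/s), >= 0.
#' @param debounce Number of consecutive supra-threshold samples required.
#' @return The onset sample index, or `NA_integer_` if no onset is found
#'   (the trial is then flagged incomplete downstream).
#' @export
detect_onset <- function(velocity, eps = 0, debounce = 1L) {
  stopifnot(eps >= 0, debounce >= 1L)
  above <- velocity > eps
  if (debounce == 1L) {
    idx <- which(above)
    return(if (length(idx)) idx[1] else NA_integer_)
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= debounce)
  if (!length(hit)) return(NA_integer_)
  ends[hit[1]] - r$lengths[hit[1]] + 1L
}

#' Detect movement end (target acquisition)
#'
#' The trial is finished at the first sample at or after onset where the
#' cursor position is strictly greater than 95% of the target position.
#' Ties at exactly the threshold do not terminate the movement.
#'
#' @param trial A [trial()] object.
#' @param onset Onset sample index from [detect_onset()].
#' @param threshold_frac Completion fraction of the target distance
#'   defining acquisition (default 0.95).
#' @return The end sample index, or `NA_integer_` if the threshold is never
#'   crossed within the trial (incomplete trial).
#' @export
detect_end <- function(trial, onset, threshold_frac = 0.95) {
  stopifnot(inherits(trial, "trial"), is.finite(onset), onset >= 1L)
  thr <- threshold_frac * trial$target_distance
  idx <- which(trial$positions[onset:length(trial$positions)] > thr)
  if (!length(idx)) return(NA_integer_)
  onset + idx[1] - 1L
}

#' Peak velocity and its timing within the movement
#'
#' Maximum of the velocity series over the onset-to-end segment, and the
#' time of that maximum relative to onset. Ties are broken by the earliest
#' index.
#'
#' @param velocity Velocity series.
#' @param times Sample times (s).
#' @param onset,end Segment bounds (sample indices), onset <= end.
#' @return A list with `peak_velocity` (%/s) and `time_to_peak` (s from
#'   onset).
#' @export
peak_velocity_and_time <- function(velocity, times, onset, end) {
  if (is.na(onset) || is.na(end) || end < onset) {
    stop("peak velocity is undefined without a completed onset-to-end segment")
  }
  seg <- velocity[onset:end]
  k <- which.max(seg) # which.max returns the first maximum: earliest tie wins
  list(peak_velocity = seg[k],
       time_to_peak = times[onset + k - 1L] - times[onset])
}

#' RMS position error against a minimum-jerk reference
#'
#' Root-mean-square deviation between an observed trajectory segment
#' (re-based so onset is time zero) and a minimum-jerk reference trace,
#' evaluated on the reference's time grid. The observed trace is linearly
#' interpolated onto that grid; beyond its last sample the observed value is
#' held constant (the cursor has settled).
#'
#' @param times,positions Observed segment, with `times[1]` at onset = 0 s.
#' @param reference A `reference_trace` from [sample_mjt()], built with the
#'   condition's mean time to target as duration.
#' @return Scalar RMSE in % workspace width.
#' @export
position_error <- function(times, positions, reference) {
  stopifnot(inherits(reference, "reference_trace"))
  obs <- stats::approx(times, positions, xout = reference$times,
                       rule = 2)$y
  sqrt(mean((obs - reference$positions)^2))
}

#' Path efficiency of a movement segment
#'
#' Ratio (in %) of the ideal path length (straight line from the position at
#' onset to the target centre) to the actually traversed path length
#' (sum of absolute position increments from onset to end). Subjects that
#' settle at the near edge of the target travel less than the ideal path,
#' giving efficiencies above 100%; the literal inverse ratio is available
#' via `mode = "actual-over-ideal"`.
#'
#' @param trial A [trial()] object.
#' @param onset,end Segment bounds (sample indices).
#' @param mode `"ideal-over-actual"` (default) or `"actual-over-ideal"`.
#' @return Path efficiency in %.
#' @export
path_efficiency <- function(trial, onset, end,
                            mode = c("ideal-over-actual", "actual-over-ideal")) {
  mode <- match.arg(mode)
  if (is.na(onset) || is.na(end) || end < onset) {
    stop("path efficiency is undefined for an incomplete trial")
  }
  seg <- trial$positions[onset:end]
  actual <- sum(abs(diff(seg)))
  ideal <- abs(trial$target_distance - seg[1])
  if (actual == 0) stop("zero traversed path length; path efficiency undefined")
  if (mode == "ideal-over-actual") 100 * ideal / actual else 100 * actual / ideal
}

#' Completion curve
#'
#' For each time in `time_grid`, the fraction of trials that were completed
#' with a time to target no greater than that time. Incomplete trials count
#' in the denominator, never the numerator, so the curve saturates at the
#' overall completion rate.
#'
#' @param metrics A per-trial metrics data frame from [compute_metrics()].
#' @param time_grid Numeric vector of times (s).
#' @return A data frame with columns `time` and `fraction_completed`
#'   (nondecreasing, in \[0, 1\]).
#' @export
completion_curve <- function(metrics, time_grid = seq(0, 10, by = 1 / 60)) {
  stopifnot(nrow(metrics) >= 1L)
  ttt <- metrics$time_to_target[metrics$completed]
  frac <- vapply(time_grid, function(t) sum(ttt <= t) / nrow(metrics),
                 numeric(1))
  data.frame(time = time_grid, fraction_completed = frac)
}

#' Normalise metrics to the smallest movement distance
#'
#' Within each modality, divides every completed trial's peak velocity and
#' time to target by the mean of that quantity over the modality's
#' smallest-distance trials, so the smallest distance normalises to 1 by
#' construction. Also returns per-(modality, distance) ellipse summaries:
#' centre = mean normalised (time-to-target, peak-velocity) pair, axes =
#' their SDs — the usual way the distance scaling of both quantities is
#' displayed jointly.
#'
#' @param metrics Per-trial metrics data frame (completed trials are used).
#' @return A list with `trials` (metrics plus `norm_peak_velocity`,
#'   `norm_time_to_target`) and `ellipses` (one row per modality x distance).
#' @export
normalize_to_smallest_distance <- function(metrics) {
  m <- metrics[metrics$completed, , drop = FALSE]
  if (!nrow(m)) stop("no completed trials to normalise")
  out <- NULL
  for (mod in unique(m$modality)) {
    sub <- m[m$modality == mod, , drop = FALSE]
    d0 <- min(sub$target_distance)
    base <- sub[sub$target_distance == d0, , drop = FALSE]
    if (!nrow(base)) stop("no completed trials at the smallest distance for ", mod)
    sub$norm_peak_velocity <- sub$peak_velocity / mean(base$peak_velocity)
    sub$norm_time_to_target <- sub$time_to_target / mean(base$time_to_target)
    out <- rbind(out, sub)
  }
  ell <- do.call(rbind, lapply(
    split(out, list(out$modality, out$target_distance), drop = TRUE),
    function(g) data.frame(
      modality = g$modality[1], target_distance = g$target_distance[1],
      center_time = mean(g$norm_time_to_target),
      center_velocity = mean(g$norm_peak_velocity),
      sd_time = stats::sd(g$norm_time_to_target),
      sd_velocity = stats::sd(g$norm_peak_velocity))))
  rownames(ell) <- NULL
  ell <- ell[order(ell$modality, ell$target_distance), , drop = FALSE]
  list(trials = out, ellipses = ell)
}
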