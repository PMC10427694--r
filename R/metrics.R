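#' Compute per-trial kinematic metrics for a collection of trials
#'
#' Runs the segmentation and metric pipeline on every trial: velocity
#' estimation, onset detection (first positive velocity, optionally
#' debounced), end detection (first strict crossing of 95% of the target),
#' time to target, peak velocity and its timing, and path efficiency. The
#' RMS position error against the condition's minimum-jerk reference is then
#' added per (modality, distance) condition, because the reference duration
#' is the condition's mean time to target.
#'
#' Incomplete trials (no onset, or target never acquired within the trial
#' window) are kept with `completed = FALSE` and `NA` movement metrics; they
#' enter completion curves but are excluded from metric aggregation and
#' statistics.
#'
#' @param trials A list of [trial()] objects (or a `trial_set` from
#'   [read_trials()] / [generate_cohort()]).
#' @param smooth_window Odd moving-average width for velocity estimation
#'   (samples). Use 1 for noise-free data; measured data defaults to 5.
#' @param eps,debounce Onset rule parameters, see [detect_onset()].
#' @param threshold_frac Completion fraction for the end rule.
#' @param path_efficiency_mode See [path_efficiency()].
#' @param position_error_mode `"per-trial"` (default: RMSE of each trial
#'   against the condition reference, as needed for trial-level statistics)
#'   or `"mean-trace"` (RMSE of the condition's onset-aligned mean trace; the
#'   value is then repeated on each completed trial of the condition).
#' @return A data frame, one row per trial, with metadata columns
#'   (`subject_id`, `modality`, `block`, `trial_id`, `target_distance`) and
#'   metric columns (`onset_time`, `end_time`, `time_to_target`,
#'   `peak_velocity`, `time_to_peak`, `path_efficiency`, `position_error`,
#'   `completed`).
#' @export
compute_metrics <- function(trials, smooth_window = 5L, eps = 0,
                            debounce = 1L, threshold_frac = 0.95,
                            path_efficiency_mode = "ideal-over-actual",
                            position_error_mode = c("per-trial", "mean-trace")) {
  position_error_mode <- match.arg(position_error_mode)
  trials <- as_trial_list(trials)
  rows <- lapply(trials, function(tr) {
    v <- estimate_velocity(tr, smooth_window)
    onset <- detect_onset(v, eps, debounce)
    end <- if (is.na(onset)) NA_integer_ else
      detect_end(tr, onset, threshold_frac)
    completed <- !is.na(onset) && !is.na(end)
    if (completed) {
      pk <- peak_velocity_and_time(v, tr$times, onset, end)
      data.frame(
        subject_id = tr$subject_id, modality = tr$modality,
        block = tr$block, trial_id = tr$trial_id,
        target_distance = tr$target_distance,
        onset_time = tr$times[onset], end_time = tr$times[end],
        time_to_target = tr$times[end] - tr$times[onset],
        peak_velocity = pk$peak_velocity, time_to_peak = pk$time_to_peak,
        path_efficiency = path_efficiency(tr, onset, end,
                                          path_efficiency_mode),
        position_error = NA_real_, completed = TRUE)
    } else {
      data.frame(
        subject_id = tr$subject_id, modality = tr$modality,
        block = tr$block, trial_id = tr$trial_id,
        target_distance = tr$target_distance,
        onset_time = if (is.na(onset)) NA_real_ else tr$times[onset],
        end_time = NA_real_, time_to_target = NA_real_,
        peak_velocity = NA_real_, time_to_peak = NA_real_,
        path_efficiency = NA_real_, position_error = NA_real_,
        completed = FALSE)
    }
  })
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  n_inc <- sum(!metrics$completed)
  if (n_inc > 0) {
    message(n_inc, " of ", nrow(metrics),
            " trials incomplete; excluded from metric aggregation")
  }
  add_position_error(metrics, trials, smooth_window = smooth_window,
                     eps = eps, debounce = debounce,
                     mode = position_error_mode)
}

# Fill the position_error column condition by condition: the minimum-jerk
# reference for a (modality, distance) condition uses that condition's mean
# time to target as its duration.
add_position_error <- function(metrics, trials, smooth_window = 5L,
                               eps = 0, debounce = 1L,
                               mode = "per-trial") {
  key <- paste(metrics$modality, metrics$target_distance, sep = "\r")
  for (k in unique(key)) {
    rows <- which(key == k & metrics$completed)
    if (!length(rows)) next
    dist <- metrics$target_distance[rows[1]]
    dbar <- mean(metrics$time_to_target[rows])
    if (!is.finite(dbar) || dbar <= 0) next
    fs <- trial_fs(trials[[rows[1]]])
    ref <- sample_mjt(mjt_params(x0 = 0, xf = dist, d = dbar), fs = fs)
    segs <- lapply(rows, function(i) {
      onset_segment(trials[[i]], smooth_window, eps, debounce)
    })
    if (mode == "per-trial") {
      for (j in seq_along(rows)) {
        s <- segs[[j]]
        metrics$position_error[rows[j]] <-
          position_error(s$times, s$positions, ref)
      }
    } else {
      mt <- mean_trace(segs, ref$times)
      err <- position_error(mt$times, mt$positions, ref)
      metrics$position_error[rows] <- err
    }
  }
  metrics
}

# Re-base a trial's trajectory so movement onset is time zero.
onset_segment <- function(tr, smooth_window = 5L, eps = 0, debounce = 1L) {
  v <- estimate_velocity(tr, smooth_window)
  onset <- detect_onset(v, eps, debounce)
  if (is.na(onset)) return(NULL)
  idx <- onset:length(tr$times)
  list(times = tr$times[idx] - tr$times[onset], positions = tr$positions[idx])
}

# Onset-aligned mean trajectory on a common grid; traces are linearly
# interpolated and held at their last value past their end.
mean_trace <- function(segs, grid) {
  segs <- Filter(Negate(is.null), segs)
  mat <- vapply(segs, function(s) {
    stats::approx(s$times, s$positions, xout = grid, rule = 2)$y
  }, numeric(length(grid)))
  list(times = grid,
       positions = rowMeans(as.matrix(mat)),
       sd = apply(as.matrix(mat), 1, stats::sd))
}

#' Per-condition summaries
#'
#' Means and SDs of every metric per (modality, target distance), the mean
#' time to target used to instantiate that condition's minimum-jerk
#' reference, and trial counts. Computed over completed trials only;
#' incomplete counts are reported alongside.
#'
#' @param metrics Per-trial metrics data frame from [compute_metrics()].
#' @return A data frame, one row per condition.
#' @export
condition_summary <- function(metrics) {
  out <- do.call(rbind, lapply(
    split(metrics, list(metrics$modality, metrics$target_distance),
          drop = TRUE),
    function(g) {
      gc <- g[g$completed, , drop = FALSE]
      msd <- function(x) c(mean = mean(x), sd = stats::sd(x))
      data.frame(
        modality = g$modality[1], target_distance = g$target_distance[1],
        n_trials = nrow(g), n_completed = nrow(gc),
        mean_time_to_target = mean(gc$time_to_target),
        sd_time_to_target = stats::sd(gc$time_to_target),
        mean_peak_velocity = mean(gc$peak_velocity),
        sd_peak_velocity = stats::sd(gc$peak_velocity),
        mean_time_to_peak = mean(gc$time_to_peak),
        sd_time_to_peak = stats::sd(gc$time_to_peak),
        mean_position_error = mean(gc$position_error),
        sd_position_error = stats::sd(gc$position_error),
        mean_path_efficiency = mean(gc$path_efficiency),
        sd_path_efficiency = stats::sd(gc$path_efficiency))
    }))
  rownames(out) <- NULL
  out[order(out$modality, out$target_distance), , drop = FALSE]
}

#' Convert a percent-of-workspace distance to physical length
#'
#' Positions are stored exclusively in percent of workspace width; this
#' helper converts to physical units given the workspace width (e.g. a 50%
#' movement on a 27-inch-wide workspace is 13.5 inches).
#'
#' @param pct Distance(s) in % of workspace width.
#' @param workspace_width Physical workspace width (any length unit).
#' @return Length(s) in the same unit as `workspace_width`.
#' @export
pct_to_length <- function(pct, workspace_width) {
  stopifnot(is.numeric(pct), is.numeric(workspace_width), workspace_width > 0)
  pct / 100 * workspace_width
}
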