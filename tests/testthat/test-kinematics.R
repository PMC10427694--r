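test_that("velocity estimation handles constant, ramp and MJT inputs", {
  const <- trial("s", "m", 1, "t", 50, times = (0:2) / 60,
                 positions = c(0, 0, 0))
  expect_equal(estimate_velocity(const), c(0, 0, 0))

  ramp <- trial("s", "m", 1, "t", 50, times = 0:3, positions = 0:3)
  expect_equal(estimate_velocity(ramp, smooth_window = 1L), c(0, 1, 1, 1))

  # sampled minimum-jerk movement: finite-difference peak within 2% of the
  # analytic 1.875 * (xf - x0) / d
  tr <- make_mjt_trial(distance = 50, d = 1, delay = 0, window = 1)
  v <- estimate_velocity(tr, smooth_window = 1L)
  expect_lt(abs(max(v) - 1.875 * 50) / (1.875 * 50), 0.02)

  expect_error(estimate_velocity(tr, smooth_window = 2L), "odd")
})

test_that("non-uniform sampling warns and uses per-interval steps", {
  tr <- trial("s", "m", 1, "t", 50, times = c(0, 0.5, 2, 2.5),
              positions = c(0, 1, 4, 5))
  expect_warning(v <- estimate_velocity(tr), "non-uniform")
  expect_equal(v, c(0, 2, 2, 2))
})

test_that("onset detection follows the first-positive-velocity rule", {
  tr <- trial("s", "m", 1, "t", 50, times = 0:4,
              positions = c(0, 0, 0, 0.5, 1.2))
  v <- estimate_velocity(tr, smooth_window = 1L)
  expect_identical(detect_onset(v), 4L) # first positive forward difference

  expect_identical(detect_onset(rep(0, 10)), NA_integer_)

  # one spurious positive sample, then zeros, then a sustained rise:
  # debounce = 3 must skip the glitch and land on the sustained rise,
  # which exhaustive scanning locates at index 7
  v2 <- c(0, 2, 0, 0, 0, 0, 1, 1, 1, 1)
  runs <- vapply(seq_along(v2), function(i) {
    all(v2[i:min(i + 2, length(v2))] > 0) && i + 2 <= length(v2)
  }, logical(1))
  expect_identical(detect_onset(v2, eps = 0, debounce = 3L),
                   which(runs)[1])
  expect_identical(detect_onset(v2, eps = 0, debounce = 3L), 7L)
})

test_that("end detection uses a strict 95%-of-target threshold", {
  tr <- trial("s", "m", 1, "t", 50, times = 0:5 / 10,
              positions = c(0, 20, 40, 47.6, 49, 50))
  expect_identical(detect_end(tr, onset = 1L), 4L) # 47.6 > 47.5

  tie <- trial("s", "m", 1, "t", 50, times = 0:3 / 10,
               positions = c(0, 30, 47.5, 47.5))
  expect_identical(detect_end(tie, onset = 1L), NA_integer_) # ties don't end

  plateau <- trial("s", "m", 1, "t", 50, times = 0:3 / 10,
                   positions = c(0, 30, 45, 45)) # settles at 90% of target
  expect_identical(detect_end(plateau, onset = 1L), NA_integer_)

  # sampled MJT to target 50 over d = 1 s crosses 95% before t_f
  mjt <- make_mjt_trial(distance = 50, d = 1, delay = 0, window = 1.5)
  v <- estimate_velocity(mjt, smooth_window = 1L)
  onset <- detect_onset(v)
  end <- detect_end(mjt, onset)
  ttt <- mjt$times[end] - mjt$times[onset]
  expect_lt(ttt, 1)
  expect_gt(ttt, 0.75)
  # and within one grid step of the analytic crossing fraction
  expect_lt(abs(ttt - mjt_crossing_fraction(0.95)), 2 / 60)
})

test_that("peak velocity reporting breaks ties at the earliest index", {
  v <- c(0, 1, 3, 3, 2, 1)
  times <- (0:5) / 10
  pk <- peak_velocity_and_time(v, times, onset = 1L, end = 6L)
  expect_equal(pk$peak_velocity, 3)
  expect_equal(pk$time_to_peak, 0.2)

  ramp <- peak_velocity_and_time(c(0, 1, 2, 3), (0:3) / 10, 1L, 4L)
  expect_equal(ramp$peak_velocity, 3) # monotone ramp peaks at the end
  expect_error(peak_velocity_and_time(v, times, NA_integer_, 6L),
               "undefined")
})

test_that("pipeline peak timing on a noise-free MJT is at mid-movement", {
  tr <- make_mjt_trial(distance = 100, d = 1, delay = 0.3, window = 2)
  v <- estimate_velocity(tr, smooth_window = 1L)
  onset <- detect_onset(v)
  end <- detect_end(tr, onset)
  pk <- peak_velocity_and_time(v, tr$times, onset, end)
  expect_equal(pk$peak_velocity, 187.5, tolerance = 0.02)
  expect_equal(pk$time_to_peak, 0.5, tolerance = 2 / 60)
})

test_that("position error is zero for identity and |c| for a constant shift", {
  ref <- sample_mjt(mjt_params(0, 50, 1), fs = 60)
  expect_equal(position_error(ref$times, ref$positions, ref), 0)
  expect_equal(position_error(ref$times, ref$positions + 2, ref), 2)
  expect_equal(position_error(ref$times, ref$positions - 3.5, ref), 3.5)
})

test_that("position error approximates the noise SD for noisy traces", {
  set.seed(42)
  ref <- sample_mjt(mjt_params(0, 50, 1), fs = 10000)
  sigma <- 1.7
  noisy <- ref$positions + rnorm(length(ref$positions), 0, sigma)
  expect_equal(position_error(ref$times, noisy, ref), sigma,
               tolerance = 0.05)
})

test_that("path efficiency reproduces straight, short-stop and wiggly cases", {
  mono <- trial("s", "m", 1, "t", 50, times = 0:5 / 10,
                positions = c(0, 10, 25, 40, 48, 50))
  expect_equal(path_efficiency(mono, 1L, 6L), 100)

  # stopping at the near target edge: traversed 47.5 for an ideal 50
  short <- trial("s", "m", 1, "t", 50, times = 0:4 / 10,
                 positions = c(0, 20, 40, 47.4, 47.6))
  end <- detect_end(short, 1L)
  expect_equal(path_efficiency(short, 1L, end), 100 * 50 / 47.6)
  expect_gt(path_efficiency(short, 1L, end), 100)

  # overshoot and return: path 0 -> 60 -> 45 -> 50 traverses 80 for ideal 50
  wig <- trial("s", "m", 1, "t", 50, times = 0:3 / 10,
               positions = c(0, 60, 45, 50))
  expect_equal(path_efficiency(wig, 1L, 4L), 62.5)
  expect_equal(path_efficiency(wig, 1L, 4L, mode = "actual-over-ideal"),
               160)
})

test_that("completion curve is a nondecreasing step bounded in [0, 1]", {
  metrics <- data.frame(time_to_target = c(1, 1, 1), completed = TRUE)
  cc <- completion_curve(metrics, time_grid = c(0.5, 0.99, 1, 2))
  expect_equal(cc$fraction_completed, c(0, 0, 1, 1))

  none <- data.frame(time_to_target = NA_real_, completed = FALSE)
  expect_equal(completion_curve(none, c(1, 5))$fraction_completed, c(0, 0))

  mixed <- data.frame(time_to_target = c(0.5, 1.5, NA),
                      completed = c(TRUE, TRUE, FALSE))
  cc2 <- completion_curve(mixed, seq(0, 10, by = 0.5))
  expect_true(all(diff(cc2$fraction_completed) >= 0))
  expect_equal(max(cc2$fraction_completed), 2 / 3) # overall completion rate
})

test_that("time to target shrinks under time compression of the trajectory", {
  ttts <- vapply(c(1.6, 1.2, 0.8, 0.4), function(d) {
    tr <- make_mjt_trial(distance = 60, d = d, delay = 0.2, window = 2.5)
    v <- estimate_velocity(tr, smooth_window = 1L)
    onset <- detect_onset(v)
    tr$times[detect_end(tr, onset)] - tr$times[onset]
  }, numeric(1))
  expect_true(all(diff(ttts) < 0))
})

test_that("normalisation to the smallest distance self-normalises to 1", {
  set.seed(7)
  metrics <- data.frame(
    modality = rep(c("a", "b"), each = 30),
    target_distance = rep(rep(c(12.5, 50, 87.5), each = 10), 2),
    peak_velocity = NA_real_, time_to_target = NA_real_, completed = TRUE)
  metrics$peak_velocity <- metrics$target_distance *
    ifelse(metrics$modality == "a", 1, 2) + rnorm(60, 0, 0.5)
  metrics$time_to_target <- 0.5 + 0.01 * metrics$target_distance

  nz <- normalize_to_smallest_distance(metrics)
  base <- nz$trials[nz$trials$target_distance == 12.5, ]
  for (mod in c("a", "b")) {
    expect_equal(mean(base$norm_peak_velocity[base$modality == mod]), 1)
    expect_equal(mean(base$norm_time_to_target[base$modality == mod]), 1)
  }
  # scale invariance: doubling all metrics leaves normalised values unchanged
  m2 <- metrics
  m2$peak_velocity <- m2$peak_velocity * 2
  m2$time_to_target <- m2$time_to_target * 2
  nz2 <- normalize_to_smallest_distance(m2)
  expect_equal(nz2$trials$norm_peak_velocity, nz$trials$norm_peak_velocity)
  # peak velocity proportional to distance: largest-distance normalised value
  # approximates the distance ratio
  far <- nz$trials[nz$trials$target_distance == 87.5, ]
  expect_equal(mean(far$norm_peak_velocity[far$modality == "a"]),
               87.5 / 12.5, tolerance = 0.05)
  expect_equal(nrow(nz$ellipses), 6L)
  expect_true(all(nz$ellipses$sd_velocity >= 0))
})

test_that("metrics are invariant to mirrored (left-handed) trajectories", {
  tr <- make_mjt_trial(distance = 50, d = 1, delay = 0.4, window = 2)
  tab <- trials_to_table(list(tr))
  mir <- tab
  mir$position_pct <- 100 - mir$position_pct # right-edge start, leftward move
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(tab, f1, row.names = FALSE)
  write.csv(mir, f2, row.names = FALSE)
  m1 <- compute_metrics(read_trials(f1), smooth_window = 1L)
  m2 <- compute_metrics(read_trials(f2, mirror = "auto"), smooth_window = 1L)
  for (col in c("time_to_target", "peak_velocity", "path_efficiency",
                "position_error")) {
    expect_equal(m1[[col]], m2[[col]], tolerance = 1e-12)
  }
})
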