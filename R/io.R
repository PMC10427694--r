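#' @keywords internal
"_PACKAGE"

# Coerce a cohort / trial_set / plain list / tidy table into a list of
# trial objects.
as_trial_list <- function(x) {
  if (inherits(x, "cohort")) return(x$trials)
  if (inherits(x, "trial")) return(list(x))
  if (is.data.frame(x)) return(table_to_trials(x))
  if (is.list(x)) {
    stopifnot(all(vapply(x, inherits, logical(1), "trial")))
    return(x)
  }
  stop("cannot interpret input as trials")
}

required_cols <- c("subject_id", "modality", "block", "trial_id",
                   "target_distance_pct", "t_s", "position_pct")

# Split a tidy long table into trial objects, rejecting malformed trials.
table_to_trials <- function(df, mirror = c("none", "auto", "always")) {
  mirror <- match.arg(mirror)
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  key <- interaction(df$subject_id, df$modality, df$block, df$trial_id,
                     drop = TRUE, lex.order = TRUE)
  groups <- split(seq_len(nrow(df)), key)
  trials <- list()
  rejected <- character(0)
  for (g in groups) {
    sub <- df[g, , drop = FALSE] # file row order defines the sample sequence
    pos <- sub$position_pct
    if (mirror == "always" ||
        (mirror == "auto" &&
         pos[length(pos)] - pos[1] < 0)) {
      pos <- 100 - pos # reflect the workspace: left-handed convention
    }
    tr <- tryCatch(
      trial(sub$subject_id[1], sub$modality[1], sub$block[1],
            sub$trial_id[1], sub$target_distance_pct[1], sub$t_s, pos),
      error = function(e) e)
    if (inherits(tr, "error")) {
      rejected <- c(rejected,
                    sprintf("trial %s (rows %d-%d): %s", sub$trial_id[1],
                            min(g), max(g), conditionMessage(tr)))
    } else {
      trials[[length(trials) + 1L]] <- tr
    }
  }
  if (length(rejected)) {
    warning(length(rejected), " trial(s) rejected:\n  ",
            paste(rejected, collapse = "\n  "))
  }
  attr(trials, "rejected") <- rejected
  trials
}

#' Read trials from a tidy long CSV
#'
#' One row per sample; required columns `subject_id`, `modality`, `block`,
#' `trial_id`, `target_distance_pct`, `t_s`, `position_pct` (header
#' required, UTF-8, decimal point). Trials with non-monotone time stamps are
#' rejected with a warning naming the offending rows; the rest load.
#' `mirror = "auto"` reflects negative-going trials (left-handed convention:
#' the cursor starts at the right workspace edge) about the workspace so
#' every loaded trial starts at 0 and moves positive.
#'
#' @param path CSV file path.
#' @param mirror `"none"`, `"auto"` or `"always"`.
#' @return A list of [trial()] objects; rejected-trial messages are kept in
#'   the `"rejected"` attribute.
#' @export
read_trials <- function(path, mirror = c("none", "auto", "always")) {
  mirror <- match.arg(mirror)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  table_to_trials(df, mirror = mirror)
}

#' Write trials to the tidy long CSV schema
#'
#' @param x A `cohort`, trial list, or tidy table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(x, path) {
  df <- if (is.data.frame(x)) x else trials_to_table(x)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the per-trial metrics table
#'
#' Deterministic column order and fixed floating-point precision so that
#' identical analyses produce byte-identical files.
#'
#' @param metrics Metrics data frame from [compute_metrics()].
#' @param path Output CSV path.
#' @param digits Significant digits for numeric columns.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path, digits = 10) {
  cols <- c("subject_id", "modality", "block", "trial_id", "target_distance",
            "onset_time", "end_time", "time_to_target", "peak_velocity",
            "time_to_peak", "path_efficiency", "position_error", "completed")
  out <- metrics[, intersect(cols, names(metrics)), drop = FALSE]
  num <- vapply(out, is.numeric, logical(1)) &
    !vapply(out, is.integer, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, digits))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis and write its outputs
#'
#' Composes the whole pipeline on a set of trials: per-trial metrics,
#' condition summaries, the two-stage rank-based factorial analysis,
#' per-modality distance-scaling regressions of peak velocity / time to
#' target / position error, per-distance variance F tests across
#' modalities, Brown-Forsythe spread tests, normalised distance-scaling
#' summaries and completion curves. Results are returned and, if `out_dir`
#' is given, written as `metrics.csv`, `condition_summary.csv`,
#' `completion_curves.csv` and `report.json` (schema-versioned, with a run
#' manifest carrying version, seed, config echo, input digest and trial
#' counts — no timestamp, so outputs are byte-reproducible).
#'
#' @param trials A `cohort`, list of trials, tidy table, or CSV path.
#' @param out_dir Optional output directory (created if needed).
#' @param alpha Significance level for the two-stage interaction decision.
#' @param smooth_window Velocity smoothing window (samples; odd).
#' @param seed Seed echoed into the manifest (the analysis itself is
#'   deterministic; the seed documents the provenance of simulated inputs).
#' @param completion_grid Time grid (s) for the completion curves.
#' @return An object of class `analysis_report` (list with `metrics`,
#'   `summary`, `two_stage`, `regressions`, `variance_tests`,
#'   `spread_tests`, `normalized`, `completion`, `manifest`).
#' @export
run_report <- function(trials, out_dir = NULL, alpha = 0.05,
                       smooth_window = 5L, seed = NA_integer_,
                       completion_grid = seq(0, 10, by = 0.1)) {
  if (is.character(trials) && length(trials) == 1L) {
    trials <- read_trials(trials)
  }
  if (inherits(trials, "cohort") && is.na(seed)) seed <- trials$seed
  tl <- as_trial_list(trials)
  metrics <- compute_metrics(tl, smooth_window = smooth_window)
  comp <- metrics[metrics$completed, , drop = FALSE]
  summ <- condition_summary(metrics)
  ts <- two_stage_analysis(metrics, alpha = alpha)

  regressions <- lapply(split(comp, comp$modality), function(g) {
    list(peak_velocity = scaling_regression(g$peak_velocity,
                                            g$target_distance),
         time_to_target = scaling_regression(g$time_to_target,
                                             g$target_distance),
         position_error = scaling_regression(g$position_error,
                                             g$target_distance))
  })

  mods <- sort(unique(comp$modality))
  variance_tests <- NULL
  if (length(mods) == 2L) {
    variance_tests <- lapply(c(peak_velocity = "peak_velocity",
                               time_to_target = "time_to_target"),
      function(resp) {
        lapply(split(comp, comp$target_distance), function(g) {
          a <- g[[resp]][g$modality == mods[2]]
          b <- g[[resp]][g$modality == mods[1]]
          if (length(a) < 2L || length(b) < 2L) return(NULL)
          variance_f_test(a, b)
        })
      })
  }

  spread_tests <- NULL
  if (length(mods) >= 2L) {
    spread_tests <- list(
      time_to_target_by_modality =
        brown_forsythe(comp$time_to_target, comp$modality),
      peak_velocity_by_modality =
        brown_forsythe(comp$peak_velocity, comp$modality),
      path_efficiency_by_distance =
        lapply(split(comp, comp$modality), function(g) {
          brown_forsythe(g$path_efficiency, g$target_distance)
        }))
  }

  normalized <- normalize_to_smallest_distance(metrics)
  completion <- do.call(rbind, lapply(
    split(metrics, list(metrics$modality, metrics$target_distance),
          drop = TRUE),
    function(g) cbind(modality = g$modality[1],
                      target_distance = g$target_distance[1],
                      completion_curve(g, completion_grid))))
  rownames(completion) <- NULL

  manifest <- list(
    tool = "mjtreach", version = as.character(utils::packageVersion("mjtreach")),
    schema_version = "1.0", seed = seed,
    n_subjects = length(unique(metrics$subject_id)),
    n_trials = nrow(metrics), n_completed = sum(metrics$completed),
    n_incomplete = sum(!metrics$completed),
    input_digest = input_digest(metrics))

  report <- structure(
    list(metrics = metrics, summary = summ, two_stage = ts,
         regressions = regressions, variance_tests = variance_tests,
         spread_tests = spread_tests, normalized = normalized,
         completion = completion, manifest = manifest),
    class = "analysis_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_metrics(metrics, file.path(out_dir, "metrics.csv"))
    utils::write.csv(format_numeric(summ), file.path(out_dir,
                                                     "condition_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(format_numeric(completion),
                     file.path(out_dir, "completion_curves.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

format_numeric <- function(df, digits = 10) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  df
}

# Content digest of the analysed metrics: deterministic, dependency-free
# (sum of a simple rolling hash over the serialised table).
input_digest <- function(metrics) {
  s <- paste(utils::capture.output(utils::write.csv(format_numeric(metrics),
                                                    stdout(),
                                                    row.names = FALSE)),
             collapse = "\n")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 251)) %% 4294967291)
}

# JSON-serialisable view of the report.
report_to_json <- function(report) {
  srh_json <- function(s) {
    lapply(seq_len(nrow(s)), function(i) {
      list(term = s$term[i], df = s$df[i], h = s$h[i],
           p_value = s$p_value[i])
    })
  }
  tr_json <- function(t) list(method = t$method, statistic = t$statistic,
                              df = t$df, p_value = t$p_value)
  two_stage <- lapply(report$two_stage, function(r) {
    s2 <- if (inherits(r$stage2, "srh_result")) srh_json(r$stage2)
          else lapply(r$stage2, tr_json)
    list(stage1 = srh_json(r$stage1), branch = r$branch, stage2 = s2)
  })
  regs <- lapply(report$regressions, function(mod) {
    lapply(mod, function(f) list(slope = f$slope, intercept = f$intercept,
                                 r_squared = f$r_squared,
                                 slope_se = f$slope_se, n = f$n))
  })
  vts <- if (is.null(report$variance_tests)) NULL else
    lapply(report$variance_tests, function(resp) {
      lapply(Filter(Negate(is.null), resp), tr_json)
    })
  sts <- if (is.null(report$spread_tests)) NULL else list(
    time_to_target_by_modality = tr_json(report$spread_tests[[1]]),
    peak_velocity_by_modality = tr_json(report$spread_tests[[2]]),
    path_efficiency_by_distance =
      lapply(report$spread_tests[[3]], tr_json))
  list(manifest = report$manifest,
       two_stage = two_stage,
       regressions = regs,
       variance_tests = vts,
       spread_tests = sts,
       normalized_ellipses = report$normalized$ellipses)
}

#' @export
print.analysis_report <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Analysis report (%s %s): %d trials, %d completed, %d incomplete\n",
              m$tool, m$version, m$n_trials, m$n_completed, m$n_incomplete))
  print(x$two_stage)
  invisible(x)
}
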