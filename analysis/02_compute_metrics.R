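#!/usr/bin/env Rscript
# Segment every trial (velocity-based onset, 95%-of-target end rule) and
# compute the per-trial kinematic metrics: time to target, peak velocity and
# its timing, RMS position error against the condition's minimum-jerk
# reference, path efficiency. Writes per-trial metrics and per-condition
# summaries.

suppressMessages(library(mjtreach))

trials <- read_trials("results/trials.csv")
metrics <- compute_metrics(trials, smooth_window = 5L)
summ <- condition_summary(metrics)

write_metrics(metrics, "results/metrics.csv")
write.csv(summ, "results/condition_summary.csv", row.names = FALSE)

cm <- metrics[metrics$completed, ]
cat(sprintf("%d/%d trials completed\n", nrow(cm), nrow(metrics)))
for (mod in sort(unique(cm$modality))) {
  g <- cm[cm$modality == mod, ]
  cat(sprintf(
    "%-14s time to target %.2f-%.2f s | peak velocity %.0f-%.0f %%/s | path efficiency %.1f%% +/- %.1f | position error %.1f-%.1f%%\n",
    mod,
    min(tapply(g$time_to_target, g$target_distance, mean)),
    max(tapply(g$time_to_target, g$target_distance, mean)),
    min(tapply(g$peak_velocity, g$target_distance, mean)),
    max(tapply(g$peak_velocity, g$target_distance, mean)),
    mean(g$path_efficiency), sd(g$path_efficiency),
    min(tapply(g$position_error, g$target_distance, mean)),
    max(tapply(g$position_error, g$target_distance, mean))))
}
cat("Wrote results/metrics.csv, results/condition_summary.csv\n")
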