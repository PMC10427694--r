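#!/usr/bin/env Rscript
# Trajectory-level summaries and figures: onset-aligned mean position and
# velocity traces with the minimum-jerk reference overlaid, peak velocity
# versus distance, normalised time-to-target/peak-velocity ellipses,
# completion curves and path-efficiency distributions.

suppressMessages({
  library(mjtreach)
  have_ggplot <- requireNamespace("ggplot2", quietly = TRUE)
})

trials <- read_trials("results/trials.csv")
metrics <- compute_metrics(trials, smooth_window = 5L)
cm <- metrics[metrics$completed, ]
nz <- normalize_to_smallest_distance(metrics)
write.csv(nz$ellipses, "results/normalized_ellipses.csv", row.names = FALSE)

nsd <- sapply(sort(unique(cm$modality)), function(mod) {
  keep <- vapply(trials, function(tr) {
    tr$modality == mod && tr$target_distance == 50
  }, logical(1))
  estimate_trajectory_noise_sd(trials[keep])
})
cat("Estimated trajectory-noise SD at the 50% target (% width):\n")
print(round(nsd, 2))

if (have_ggplot) {
  library(ggplot2)
  dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

  comp <- do.call(rbind, lapply(
    split(metrics, metrics$modality),
    function(g) cbind(modality = g$modality[1],
                      completion_curve(g, seq(0, 4, by = 0.05)))))
  ggsave("results/figures/completion_curves.pdf", width = 6, height = 4,
         plot = ggplot(comp, aes(time, fraction_completed,
                                 colour = modality)) +
           geom_step() +
           labs(x = "time from onset (s)", y = "fraction of trials completed"))

  ggsave("results/figures/peak_velocity_vs_distance.pdf", width = 6,
         height = 4,
         plot = ggplot(cm, aes(factor(target_distance), peak_velocity,
                               fill = modality)) +
           geom_violin(position = position_dodge(0.8), scale = "width") +
           labs(x = "movement distance (% workspace width)",
                y = "peak velocity (%/s)"))

  ggsave("results/figures/normalized_ellipses.pdf", width = 6, height = 4,
         plot = ggplot(nz$ellipses,
                       aes(center_velocity, center_time,
                           colour = factor(target_distance),
                           shape = modality)) +
           geom_point(size = 3) +
           geom_errorbar(aes(ymin = center_time - sd_time,
                             ymax = center_time + sd_time), width = 0.05) +
           geom_errorbarh(aes(xmin = center_velocity - sd_velocity,
                              xmax = center_velocity + sd_velocity),
                          height = 0.02) +
           labs(x = "normalised peak velocity", y = "normalised time to target",
                colour = "distance (%)"))

  ggsave("results/figures/path_efficiency.pdf", width = 6, height = 4,
         plot = ggplot(cm, aes(factor(target_distance), path_efficiency,
                               fill = modality)) +
           geom_boxplot(position = position_dodge(0.8)) +
           geom_hline(yintercept = 100, linetype = 2) +
           labs(x = "movement distance (% workspace width)",
                y = "path efficiency (%)"))
  cat("Wrote results/figures/*.pdf\n")
}
cat("Wrote results/normalized_ellipses.csv\n")
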