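#!/usr/bin/env Rscript
# Simulate the study cohort: 10 participants, two control modalities
# (manipulandum-like and sonomyography-like), 5 analysis blocks of 7 targets
# at 12.5-87.5% of workspace width, 60 Hz, 10 s trial windows. Writes the
# tidy trial table, the generator ground truth, and a config echo.

suppressMessages(library(mjtreach))
seed <- 20260

cfg <- session_config()
co <- suppressWarnings(generate_cohort(cfg, seed = seed))

dir.create("results", showWarnings = FALSE)
write_trials(co, "results/trials.csv")
write.csv(co$truth, "results/ground_truth.csv", row.names = FALSE)
jsonlite::write_json(c(unclass(cfg), seed = seed), "results/config.json",
                     auto_unbox = TRUE, pretty = TRUE)

cat(sprintf("Simulated %d trials (%d subjects x %s x %d blocks x %d targets)\n",
            length(co$trials), cfg$n_subjects,
            paste(cfg$modalities, collapse = "+"), cfg$n_blocks,
            length(cfg$target_distances)))
cat("Wrote results/trials.csv, results/ground_truth.csv, results/config.json\n")
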