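Package: mjtreach
Title: Minimum-Jerk Trajectory Analysis of Point-to-Point Cursor Reaching
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing one-dimensional point-to-point cursor
    trajectories from target-acquisition tasks driven by different control
    modalities (e.g. a hand-held manipulandum or sonomyographic muscle
    imaging). Provides the closed-form minimum-jerk trajectory model
    (position, velocity, jerk cost), movement segmentation (velocity-based
    onset, 95-percent-of-target end rule), per-trial kinematic metrics (time
    to target, peak velocity and its timing, RMS position error against the
    minimum-jerk reference, path efficiency, completion curves), a
    rank-based two-factor Scheirer-Ray-Hare test with the two-stage
    follow-up logic (interaction-conditional Kruskal-Wallis), spread tests
    (Brown-Forsythe, variance F), distance-scaling regressions, and a
    seeded synthetic-cohort generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    ggplot2
Config/testthat/edition: 3
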