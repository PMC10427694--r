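# Noise-free trial following the minimum-jerk trajectory exactly: flat
# pre-movement segment, sampled MJT, hold at the endpoint.
make_mjt_trial <- function(distance = 50, d = 1, fs = 60, delay = 0.5,
                           window = 3, endpoint = distance,
                           subject_id = "S01", modality = "synthetic",
                           block = 1L, trial_id = "T001") {
  times <- seq(0, window, by = 1 / fs)
  p <- mjt_params(x0 = 0, xf = endpoint, d = d, t_s = delay)
  x <- numeric(length(times))
  moving <- times >= delay & times <= delay + d
  x[moving] <- mjt_position(p, times[moving])
  x[times > delay + d] <- endpoint
  trial(subject_id, modality, block, trial_id, distance, times, x)
}

# Balanced factorial table of synthetic responses: additive or interacting
# modality x distance structure plus Gaussian noise. The interacting
# structure uses opposite distance trends per modality (a crossing,
# non-removable interaction): a monotone-separable interaction would be
# rank-additive and invisible to a rank-based test by design.
make_factorial <- function(n_per_cell = 5, effect = c("additive",
                                                      "interaction",
                                                      "null"),
                           noise_sd = 1) {
  effect <- match.arg(effect)
  distances <- c(12.5, 25, 37.5, 50, 62.5, 75, 87.5)
  g <- expand.grid(modality = c("manipulandum", "sonomyography"),
                   distance = distances, rep = seq_len(n_per_cell))
  mu <- switch(effect,
    additive = 0.1 * g$distance + ifelse(g$modality == "sonomyography", 3, 0),
    interaction = 0.1 * ifelse(g$modality == "sonomyography",
                               100 - g$distance, g$distance),
    null = 0)
  g$response <- mu + rnorm(nrow(g), 0, noise_sd)
  g
}

# Independent oracle for the Scheirer-Ray-Hare statistic: classical two-way
# ANOVA computed on the jointly rank-transformed responses, each term's SS
# divided by the total rank mean square.
srh_oracle <- function(response, a, b) {
  r <- rank(response)
  a <- factor(a); b <- factor(b)
  tab <- stats::anova(stats::aov(r ~ a * b))
  ms_total <- sum(tab$`Sum Sq`) / (length(r) - 1)
  h <- tab$`Sum Sq`[1:3] / ms_total
  names(h) <- c("modality", "distance", "modality:distance")
  h
}
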