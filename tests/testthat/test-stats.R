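test_that("SRH H values match the ANOVA-on-ranks oracle on random tables", {
  set.seed(101)
  for (rep in 1:20) {
    tab <- make_factorial(n_per_cell = 5,
                          effect = sample(c("additive", "interaction",
                                            "null"), 1))
    s <- srh_test(tab$response, tab$modality, tab$distance)
    h_oracle <- srh_oracle(tab$response, tab$modality, tab$distance)
    expect_equal(s$h, unname(h_oracle[s$term]), tolerance = 1e-10)
    expect_equal(s$df, c(1L, 6L, 6L))
  }
})

test_that("SRH sequential decomposition closes and handles ties", {
  set.seed(11)
  tab <- make_factorial(5, "additive")
  tab$response <- round(tab$response) # force heavy ties
  s <- srh_test(tab$response, tab$modality, tab$distance)
  r <- rank(tab$response)
  ss_total <- sum((r - mean(r))^2)
  # term SS + residual SS = total SS on ranks
  fit <- stats::aov(r ~ factor(tab$modality) * factor(tab$distance))
  expect_equal(sum(s$ss) + sum(stats::residuals(fit)^2), ss_total,
               tolerance = 1e-9)
  # tie-corrected agreement with the oracle holds under ties too
  expect_equal(s$h, unname(srh_oracle(tab$response, tab$modality,
                                      tab$distance)[s$term]),
               tolerance = 1e-10)
})

test_that("SRH is invariant under strictly monotone response transforms", {
  set.seed(5)
  tab <- make_factorial(4, "interaction")
  s1 <- srh_test(tab$response, tab$modality, tab$distance)
  s2 <- srh_test(exp(tab$response / 10), tab$modality, tab$distance)
  s3 <- srh_test(rank(tab$response)^3, tab$modality, tab$distance)
  expect_equal(s1$h, s2$h)
  expect_equal(s1$h, s3$h)
})

test_that("SRH on unbalanced tables still closes to the sequential ANOVA", {
  set.seed(21)
  tab <- make_factorial(5, "additive")
  tab <- tab[-sample(nrow(tab), 13), ] # knock out rows to unbalance cells
  s <- srh_test(tab$response, tab$modality, tab$distance)
  r <- rank(tab$response)
  a <- factor(tab$modality); b <- factor(tab$distance)
  tabss <- stats::anova(stats::aov(r ~ a * b)) # sequential (Type-I) SS
  expect_equal(s$ss, tabss$`Sum Sq`[1:3], tolerance = 1e-9)
})

test_that("a strong distance effect with identical modalities splits cleanly", {
  # responses strictly increasing with distance, identical across modalities
  distances <- rep(rep(c(12.5, 25, 37.5, 50, 62.5, 75, 87.5), each = 5), 2)
  modality <- rep(c("m", "s"), each = 35)
  response <- distances + rep(seq(0, 0.4, length.out = 5), 14) # no noise
  s <- srh_test(response, modality, distances)
  expect_lt(s$p_value[s$term == "distance"], 1e-3)
  expect_lt(s$h[s$term == "modality"], 1)
  expect_equal(s$h, unname(srh_oracle(response, modality,
                                      distances)[s$term]),
               tolerance = 1e-10)
})

test_that("all-tied responses give the degenerate H = 0, p = 1 result", {
  tab <- make_factorial(3, "null", noise_sd = 0)
  s <- srh_test(tab$response, tab$modality, tab$distance)
  expect_true(attr(s, "degenerate"))
  expect_equal(s$h, c(0, 0, 0))
  expect_equal(s$p_value, c(1, 1, 1))
})

test_that("collapsing one factor reduces SRH to the Kruskal-Wallis H", {
  set.seed(33)
  tab <- make_factorial(5, "additive")
  one <- tab[tab$modality == "manipulandum", ]
  expect_warning(
    s <- srh_test(one$response, one$modality, one$distance),
    "single level")
  kw <- kruskal_wallis(one$response, one$distance)
  expect_equal(s$h[s$term == "distance"], kw$statistic, tolerance = 1e-10)
  expect_equal(s$df[s$term == "distance"], kw$df)
})

test_that("kruskal_wallis matches the exhaustive small-sample statistic", {
  # groups {1,2,3} vs {4,5,6}: enumerate all 20 rank splits to locate the
  # observed H in the exact permutation distribution
  x <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("a", "b"), each = 3)
  kw <- kruskal_wallis(x, g)
  splits <- utils::combn(6, 3)
  h_all <- apply(splits, 2, function(idx) {
    r <- rank(x)
    n <- 6
    12 / (n * (n + 1)) *
      (sum(r[idx])^2 / 3 + sum(r[-idx])^2 / 3) - 3 * (n + 1)
  })
  expect_equal(kw$statistic, max(h_all), tolerance = 1e-12)
  expect_equal(kw$p_value,
               stats::kruskal.test(x, factor(g))$p.value)
  # identical groups carry no information
  expect_equal(kruskal_wallis(c(1, 2, 3, 1, 2, 3),
                              rep(c("a", "b"), each = 3))$statistic, 0)
  expect_equal(kruskal_wallis(rep(5, 6), g)$statistic, 0)
})

test_that("Brown-Forsythe equals the ANOVA F on absolute median deviations", {
  x <- c(1, 2, 4, 10, 20, 31) # a 2 x 3 toy table, spreads clearly unequal
  g <- rep(c("a", "b"), each = 3)
  bf <- brown_forsythe(x, g)
  z <- abs(x - rep(tapply(x, g, median), each = 3))
  man <- stats::anova(stats::lm(z ~ factor(g)))
  expect_equal(bf$statistic, man$`F value`[1], tolerance = 1e-12)
  expect_equal(bf$p_value, man$`Pr(>F)`[1], tolerance = 1e-12)
  # agreement with the dedicated implementation in car
  skip_if_not_installed("car")
  lev <- car::leveneTest(x, factor(g), center = median)
  expect_equal(bf$statistic, lev$`F value`[1], tolerance = 1e-12)
})

test_that("Brown-Forsythe accepts equal spreads and detects unequal ones", {
  set.seed(13)
  a <- rnorm(50); b <- a + 7 # pure location shift
  bf0 <- brown_forsythe(c(a, b), rep(c("a", "b"), each = 50))
  expect_gt(bf0$p_value, 0.9)
  x <- c(rnorm(50, sd = 1), rnorm(50, sd = 5))
  bf1 <- brown_forsythe(x, rep(c("a", "b"), each = 50))
  expect_lt(bf1$p_value, 0.05)
  expect_error(brown_forsythe(c(1, 2, 3), c("a", "a", "b")),
               "at least 2")
})

test_that("variance F test follows the scale rule and is calibrated", {
  a <- c(1, 3, 5, 7, 9)
  expect_equal(variance_f_test(a, a)$statistic, 1)
  expect_equal(variance_f_test(a, 2 * a)$statistic, 0.25)
  expect_error(variance_f_test(a, rep(1, 5)), "zero variance")

  set.seed(99)
  rej <- mean(replicate(4000, {
    variance_f_test(rnorm(10), rnorm(10))$p_value < 0.05
  }))
  expect_gt(rej, 0.035)
  expect_lt(rej, 0.065)
})

test_that("scaling regression recovers exact and noisy linear relations", {
  d <- rep(c(12.5, 25, 50, 87.5), each = 3)
  fit <- scaling_regression(1.08 * d, d)
  expect_equal(fit$slope, 1.08)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)

  flat <- scaling_regression(rep(3, 12), d)
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)

  set.seed(2)
  y <- 2 + 0.01 * d + rnorm(12, 0, 0.05)
  noisy <- scaling_regression(y, d)
  expect_lt(abs(noisy$slope - 0.01), 3 * noisy$slope_se)
  expect_error(scaling_regression(1:5, rep(10, 5)), "distinct")
})

test_that("two-stage analysis takes the interaction-conditional branch", {
  set.seed(55)
  wrap <- function(tab) {
    data.frame(modality = tab$modality, target_distance = tab$distance,
               peak_velocity = tab$response, time_to_target = tab$response,
               position_error = tab$response, time_to_peak = tab$response,
               completed = TRUE)
  }
  add <- two_stage_analysis(wrap(make_factorial(5, "additive")),
                            responses = "peak_velocity")
  expect_equal(add$peak_velocity$branch, "srh-no-interaction")
  expect_s3_class(add$peak_velocity$stage2, "srh_result")
  expect_false("modality:distance" %in% add$peak_velocity$stage2$term)

  int <- two_stage_analysis(wrap(make_factorial(5, "interaction")),
                            responses = "peak_velocity")
  expect_equal(int$peak_velocity$branch, "kruskal-wallis-by-modality")
  expect_length(int$peak_velocity$stage2, 2L)

  # alpha = 1 forces the Kruskal-Wallis branch regardless of the data
  forced <- two_stage_analysis(wrap(make_factorial(5, "additive")),
                               responses = "peak_velocity", alpha = 1)
  expect_equal(forced$peak_velocity$branch, "kruskal-wallis-by-modality")

  # exactly one stage-2 outcome per response variable
  all4 <- two_stage_analysis(wrap(make_factorial(5, "interaction")))
  expect_named(all4, c("peak_velocity", "time_to_target",
                       "position_error", "time_to_peak"))
  expect_true(all(vapply(all4, function(r) !is.null(r$stage2), logical(1))))
})

test_that("two-stage branching is reliable over repeated simulated cohorts", {
  set.seed(77)
  n_runs <- 100
  additive_ok <- interaction_ok <- 0
  for (i in seq_len(n_runs)) {
    ta <- make_factorial(5, "additive")
    ti <- make_factorial(5, "interaction")
    sa <- srh_test(ta$response, ta$modality, ta$distance)
    si <- srh_test(ti$response, ti$modality, ti$distance)
    additive_ok <- additive_ok +
      (sa$p_value[sa$term == "modality:distance"] >= 0.05)
    interaction_ok <- interaction_ok +
      (si$p_value[si$term == "modality:distance"] < 0.05)
  }
  expect_gte(additive_ok, 95)
  expect_gte(interaction_ok, 95)
})
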