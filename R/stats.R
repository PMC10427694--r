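#' Scheirer-Ray-Hare rank-based two-factor test
#'
#' The multi-factor extension of the Kruskal-Wallis test: all responses are
#' jointly rank-transformed (average ranks for ties), a two-way
#' sum-of-squares decomposition is computed on the ranks, and each term's
#' statistic is \eqn{H = SS_{term} / MS_{total}} with
#' \eqn{MS_{total} = SS_{total}/(N-1)}. Computing \eqn{MS_{total}} from the
#' empirical rank variance applies the standard tie correction implicitly
#' (tied ranks shrink the total sum of squares exactly as the correction
#' factor prescribes). P-values come from the chi-square distribution at the
#' term's degrees of freedom: \eqn{a-1} and \eqn{b-1} for the main effects
#' and \eqn{(a-1)(b-1)} for the interaction.
#'
#' For unbalanced designs the decomposition uses sequential (Type-I) sums of
#' squares with terms ordered modality, distance, interaction; for the
#' balanced designs of the task the sequential and marginal decompositions
#' coincide. A factor with a single level is tolerated with a warning (its
#' SS and the interaction SS are zero/absent), which makes the test collapse
#' to a Kruskal-Wallis test on the remaining factor.
#'
#' @param response Numeric response vector (one value per trial).
#' @param modality,distance Factor-like vectors of the two design factors.
#' @param include_interaction If `FALSE` the interaction SS is pooled into
#'   the residual and only the main effects are tested.
#' @return An object of class `srh_result`: a data frame with one row per
#'   term (`term`, `df`, `ss`, `h`, `p_value`) plus attributes `n`,
#'   `ms_total` and `degenerate`.
#' @seealso [kruskal_wallis()], [two_stage_analysis()]
#' @export
srh_test <- function(response, modality, distance,
                     include_interaction = TRUE) {
  ok <- is.finite(response)
  if (!all(ok)) stop("responses must be finite")
  a <- factor(modality)
  b <- factor(distance)
  n <- length(response)
  stopifnot(length(a) == n, length(b) == n, n >= 3L)
  if (nlevels(a) < 2L || nlevels(b) < 2L) {
    warning("a factor has a single level; its effect (and the interaction) ",
            "is not estimable and the test reduces to one factor")
  }
  r <- rank(response)
  ss_total <- sum((r - mean(r))^2)
  if (ss_total == 0) {
    # all responses tied: no rank variance, nothing to test
    terms <- c("modality", "distance",
               if (include_interaction) "modality:distance")
    df <- c(nlevels(a) - 1L, nlevels(b) - 1L,
            if (include_interaction) (nlevels(a) - 1L) * (nlevels(b) - 1L))
    out <- data.frame(term = terms, df = df, ss = 0, h = 0, p_value = 1)
    return(structure(out, class = c("srh_result", "data.frame"),
                     n = n, ms_total = 0, degenerate = TRUE))
  }
  ms_total <- ss_total / (n - 1)
  ss <- rank_ss_decomposition(r, a, b, include_interaction)
  h <- ss$ss / ms_total
  out <- data.frame(term = ss$term, df = ss$df, ss = ss$ss, h = h,
                    p_value = ifelse(ss$df > 0,
                                     stats::pchisq(h, ss$df,
                                                   lower.tail = FALSE), 1))
  structure(out, class = c("srh_result", "data.frame"),
            n = n, ms_total = ms_total, degenerate = FALSE)
}

# Sequential (Type-I) sum-of-squares decomposition of the ranks r over
# factors a then b then a:b. For balanced designs this equals the classical
# closed-form decomposition from cell and margin means, which is used
# directly (it is exact and much cheaper); otherwise successive least-squares
# fits on explicit dummy design matrices measure each term's RSS reduction.
rank_ss_decomposition <- function(r, a, b, include_interaction) {
  cell <- table(a, b)
  balanced <- length(unique(as.vector(cell))) == 1L && all(cell > 0)
  df_a <- nlevels(a) - 1L
  df_b <- nlevels(b) - 1L
  df_ab <- df_a * df_b
  if (balanced) {
    gm <- mean(r)
    na <- tabulate(a)
    nb <- tabulate(b)
    ma <- rowsum(r, a) / na
    mb <- rowsum(r, b) / nb
    ss_a <- sum(na * (ma - gm)^2)
    ss_b <- sum(nb * (mb - gm)^2)
    mab <- rowsum(r, interaction(a, b, drop = TRUE))
    nab <- tabulate(interaction(a, b, drop = TRUE))
    ss_cells <- sum(nab * (mab / nab - gm)^2)
    ss_ab <- ss_cells - ss_a - ss_b
  } else {
    rss <- function(X) {
      fit <- stats::lm.fit(X, r)
      sum(fit$residuals^2)
    }
    dummies <- function(f) {
      if (nlevels(f) < 2L) return(matrix(0, length(f), 0L))
      stats::model.matrix(~f)[, -1, drop = FALSE]
    }
    one <- matrix(1, length(r))
    Xa <- cbind(one, dummies(a))
    Xab <- cbind(Xa, dummies(b))
    # the cell-means design spans the full two-way model with interaction
    Xfull <- stats::model.matrix(~ 0 + interaction(a, b, drop = TRUE))
    rss0 <- rss(one)
    rss_a <- rss(Xa)
    rss_b <- rss(Xab)
    ss_a <- rss0 - rss_a
    ss_b <- rss_a - rss_b
    ss_ab <- rss_b - rss(Xfull)
  }
  if (include_interaction) {
    data.frame(term = c("modality", "distance", "modality:distance"),
               df = c(df_a, df_b, df_ab),
               ss = c(ss_a, ss_b, ss_ab))
  } else {
    data.frame(term = c("modality", "distance"),
               df = c(df_a, df_b),
               ss = c(ss_a, ss_b))
  }
}

#' @export
print.srh_result <- function(x, ...) {
  cat("Scheirer-Ray-Hare rank test (N =", attr(x, "n"), ")\n")
  if (isTRUE(attr(x, "degenerate"))) {
    cat("  degenerate design: all responses tied; H = 0, p = 1\n")
  }
  df <- as.data.frame(x)
  df$h <- signif(df$h, 6)
  df$p_value <- signif(df$p_value, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Kruskal-Wallis test returning a tidy result
#'
#' Thin wrapper over [stats::kruskal.test()] (tie-corrected H, chi-square
#' p-value at k-1 degrees of freedom) returning the package's common
#' `test_result` shape. With all values tied the statistic is defined as 0
#' with p = 1 rather than an error.
#'
#' @param response Numeric responses.
#' @param group Grouping factor (>= 2 non-empty groups).
#' @return A `test_result` list: `statistic`, `df`, `p_value`, `method`.
#' @export
kruskal_wallis <- function(response, group) {
  group <- factor(group)
  stopifnot(nlevels(group) >= 2L, length(response) == length(group))
  if (length(unique(response)) == 1L) {
    return(test_result(0, nlevels(group) - 1L, 1, "Kruskal-Wallis"))
  }
  kt <- stats::kruskal.test(response, group)
  test_result(unname(kt$statistic), unname(kt$parameter), kt$p.value,
              "Kruskal-Wallis")
}

#' Brown-Forsythe test for equality of spread
#'
#' One-way ANOVA F on absolute deviations from the group medians: robust to
#' non-normality, sensitive to unequal spread. Each group needs at least 2
#' observations.
#'
#' @param response Numeric responses.
#' @param group Grouping factor (>= 2 groups, each of size >= 2).
#' @return A `test_result` with `statistic` (F), `df` (numerator,
#'   denominator), `p_value`, `method`.
#' @export
brown_forsythe <- function(response, group) {
  group <- factor(group)
  stopifnot(nlevels(group) >= 2L, length(response) == length(group))
  if (any(tabulate(group) < 2L)) {
    stop("Brown-Forsythe needs at least 2 observations per group")
  }
  med <- tapply(response, group, stats::median)
  z <- abs(response - med[group])
  ow <- stats::oneway.test(z ~ group, var.equal = TRUE)
  test_result(unname(ow$statistic), unname(ow$parameter), ow$p.value,
              "Brown-Forsythe")
}

#' Two-sample variance F test
#'
#' \eqn{F = s_a^2 / s_b^2} with \eqn{(n_a - 1, n_b - 1)} degrees of freedom;
#' two-sided by default. Wraps [stats::var.test()].
#'
#' @param a,b Numeric samples (each >= 2 observations).
#' @param alternative Passed to [stats::var.test()].
#' @return A `test_result`.
#' @export
variance_f_test <- function(a, b, alternative = "two.sided") {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::var(b) == 0) stop("zero variance in denominator group")
  vt <- stats::var.test(a, b, alternative = alternative)
  test_result(unname(vt$statistic), unname(vt$parameter), vt$p.value,
              "variance-F")
}

test_result <- function(statistic, df, p_value, method) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.6g, df = %s, p = %.4g\n",
              x$method, x$statistic, paste(signif(x$df, 6), collapse = ", "),
              x$p_value))
  invisible(x)
}

#' Ordinary least-squares scaling regression of a metric on distance
#'
#' Fits `metric ~ distance` by OLS and reports the slope (response units per
#' % of workspace width), intercept, R-squared and the slope's standard
#' error; used for the distance-scaling summaries (e.g. peak velocity and
#' time to target versus movement distance).
#'
#' @param metric Numeric response per trial.
#' @param distance Movement distance per trial (% workspace width), with at
#'   least 2 distinct values.
#' @return An object of class `regression_fit`: list with `slope`,
#'   `intercept`, `r_squared`, `slope_se`, `n`.
#' @export
scaling_regression <- function(metric, distance) {
  stopifnot(length(metric) == length(distance))
  keep <- is.finite(metric) & is.finite(distance)
  metric <- metric[keep]
  distance <- distance[keep]
  if (length(unique(distance)) < 2L) {
    stop("scaling regression needs at least 2 distinct distances")
  }
  if (stats::var(metric) == 0) {
    return(structure(list(slope = 0, intercept = metric[1], r_squared = 0,
                          slope_se = 0, n = length(metric)),
                     class = "regression_fit"))
  }
  fit <- stats::lm(metric ~ distance)
  sm <- suppressWarnings(summary(fit)) # exact fits trip a harmless warning
  r2 <- sm$r.squared
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (is.nan(r2)) 0 else r2,
                 slope_se = sm$coefficients[2, 2],
                 n = length(metric)),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(
    "OLS scaling fit (n = %d): slope = %.4g (SE %.3g), intercept = %.4g, R^2 = %.3g\n",
    x$n, x$slope, x$slope_se, x$intercept, x$r_squared))
  invisible(x)
}

#' Two-stage rank-based factorial analysis
#'
#' Stage 1 runs a Scheirer-Ray-Hare test with interaction for each response
#' variable. Stage 2 depends on the interaction term: if it is not
#' significant at `alpha`, the SRH test is re-run without the interaction
#' term; if it is significant, the factorial question is replaced by two
#' Kruskal-Wallis tests over distance, one per modality subset (modality is
#' held fixed to keep the number of follow-up tests small).
#'
#' @param metrics Per-trial metrics data frame from [compute_metrics()]
#'   (incomplete trials are dropped).
#' @param responses Character vector of metric columns to analyse.
#' @param alpha Significance level for the interaction decision.
#' @return An object of class `two_stage_result`: a named list per response
#'   with elements `stage1` (`srh_result`), `branch`
#'   (`"srh-no-interaction"` or `"kruskal-wallis-by-modality"`) and `stage2`.
#' @export
two_stage_analysis <- function(metrics,
                               responses = c("peak_velocity",
                                             "time_to_target",
                                             "position_error",
                                             "time_to_peak"),
                               alpha = 0.05) {
  m <- metrics[metrics$completed, , drop = FALSE]
  stopifnot(nrow(m) >= 4L, all(responses %in% names(m)))
  out <- lapply(responses, function(resp) {
    y <- m[[resp]]
    s1 <- srh_test(y, m$modality, m$target_distance,
                   include_interaction = TRUE)
    p_int <- s1$p_value[s1$term == "modality:distance"]
    if (p_int >= alpha) {
      list(stage1 = s1, branch = "srh-no-interaction",
           stage2 = srh_test(y, m$modality, m$target_distance,
                             include_interaction = FALSE))
    } else {
      s2 <- lapply(split(seq_len(nrow(m)), m$modality), function(idx) {
        kruskal_wallis(y[idx], m$target_distance[idx])
      })
      list(stage1 = s1, branch = "kruskal-wallis-by-modality", stage2 = s2)
    }
  })
  names(out) <- responses
  structure(out, class = "two_stage_result", alpha = alpha)
}

#' @export
print.two_stage_result <- function(x, ...) {
  cat("Two-stage rank-based analysis (alpha =", attr(x, "alpha"), ")\n")
  for (resp in names(x)) {
    cat("\n==", resp, "==\n")
    print(x[[resp]]$stage1)
    cat("stage 2:", x[[resp]]$branch, "\n")
    s2 <- x[[resp]]$stage2
    if (inherits(s2, "srh_result")) print(s2)
    else for (mod in names(s2)) {
      cat(" ", mod, ": ")
      print(s2[[mod]])
    }
  }
  invisible(x)
}
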