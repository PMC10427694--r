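---
title: "Minimum-jerk analysis of point-to-point cursor reaching: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum-jerk analysis of point-to-point cursor reaching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mjtreach)
```

## The scientific question

Modern human–machine interfaces can decode a graded biosignal — for
example, the deformation state of forearm muscles imaged by ultrasound
(sonomyography) — and map it proportionally onto the position of a cursor.
Standard interface metrics (accuracy, completion rate, path length) say how
*well* users acquire targets, but not whether the movements are
*naturalistic*. Biological point-to-point reaching has a well-known
signature: a single bell-shaped velocity peak near the movement midpoint,
peak velocity growing proportionally with movement distance, and a path
close to the minimum-jerk trajectory. This package implements an analysis
pipeline that scores cursor trajectories against that signature and
compares control modalities statistically.

## The minimum-jerk model

The rest-to-rest movement from `x0` to `xf` over duration `d` that
minimises $\int_{t_s}^{t_f} \dddot{x}(t)^2\,dt$ is the quintic

$$x(t) = x_0 + (x_f - x_0)\,(10\tau^3 - 15\tau^4 + 6\tau^5), \qquad
\tau = (t - t_s)/d,$$

with velocity $v(t) = (x_f - x_0)(30\tau^2 - 60\tau^3 + 30\tau^4)/d$. Two
closed-form identities anchor the test suite: the peak velocity
$1.875\,(x_f-x_0)/d$ at $\tau = 1/2$, and the jerk cost
$720\,(x_f-x_0)^2/d^5$.

Two modelling points deserve emphasis:

- **Optimality class.** The quintic is the jerk minimiser only among
  trajectories sharing its six boundary conditions (position, velocity
  *and* acceleration zeroed at both ends). Curves that merely share the
  endpoint positions can have lower squared jerk — the smoothstep cubic
  $3\tau^2 - 2\tau^3$ has constant jerk and cost $144\,(x_f-x_0)^2/d^5$ —
  because they violate the zero-acceleration ends. The optimality tests
  therefore perturb the quintic with polynomials vanishing to second order
  at both ends, the class for which the calculus-of-variations argument
  holds.
- **Dimensionality.** All analysed trajectories are one-dimensional
  (horizontal cursor position in % of workspace width); the vector norm in
  the jerk functional reduces to a scalar square. Planar or via-point
  extensions are out of scope.

The time origin is movement onset: `mjt_params()` defaults to `t_s = 0`
and observed segments are re-based at onset before any comparison.
Evaluating the quintic outside $[t_s, t_f]$ raises an error rather than
extrapolating; a `clamp` argument saturates at the endpoints for plotting
over a longer trial window. The analytic jerk cost integrates the exact
third derivative by composite trapezoid (2001 grid points by default, ~2e-7
relative error); sampled traces use third differences centred between
samples with a constant-jerk extension into the two half-step tails, which
removes an otherwise systematic ~0.5% truncation deficit at 60 Hz.

## Segmentation and metrics

**Velocity** is estimated by backward first differences scaled by the
per-interval time step (`v[1] = 0`), optionally smoothed by a centred
moving average. The default window is 5 samples (~83 ms at 60 Hz) for
measured or noisy data and 1 (off) for noise-free synthetic traces:
finite differencing at 60 Hz amplifies sensor noise, and the onset rule
below is meaningless on raw noise. Edge samples use shrinking windows so
the series keeps its length.

**Onset** is the first sample with positive velocity — the task's literal
rule, recovered by the defaults `eps = 0`, `debounce = 1`. For noisy data
the generalisation "velocity above `eps` for `debounce` consecutive
samples" is available; both parameters are exposed rather than hidden in
heuristics.

**End** is the first sample *strictly* above 95% of the target position;
ties at the threshold do not terminate. Trials that never cross are kept as
incomplete: they enter completion curves (denominator and, never, the
numerator) but are excluded from metric aggregation and statistics, with
counts logged. **Time to target** is end minus onset.

**Position error** is the RMSE between the observed trajectory and the MJT
reference built for the trial's (modality, distance) condition, whose
duration is that condition's *mean time to target* — so the reference is a
condition-level object and position error is only defined once the cohort
is segmented. The observed segment is re-based at onset, linearly
interpolated onto the reference grid, and held at its last value beyond its
end (the cursor has settled). The default is per-trial RMSE (each trial
scored against the condition reference), because trial-level values are
what the rank tests consume; a condition-mean-trace mode computes the RMSE
of the onset-aligned mean trajectory instead, which is systematically
smaller (averaging cancels noise before squaring) and matches how
trace-level summaries are usually displayed.

**Path efficiency** is reported as ideal/actual × 100, where the ideal
path is the straight line from the onset position to the *target centre*
and the actual path is the sum of absolute increments from onset to end. A
subject who stops just past the target's near edge (95% crossing) travels
*less* than the ideal path and scores above 100% — a real phenomenon of
fixed-width targets, not an artefact — which is why the ratio is oriented
this way; the literal inverse ratio is available via
`mode = "actual-over-ideal"`.

**Direction normalisation**: trials recorded in a left-handed convention
(cursor starting at the right workspace edge, moving negative) are
reflected about the workspace (`x → 100 − x`) at load time, so every
analysed trial starts near 0 and moves positive. All metrics are invariant
under this mirroring, which the tests assert.

## The two-stage rank-based analysis

Trial metrics from fixed target sets are bounded, skewed and
heteroscedastic across conditions, so the factorial comparison uses ranks
throughout. The Scheirer–Ray–Hare (SRH) test rank-transforms all responses
jointly (average ranks for ties), decomposes the rank sums of squares over
modality, distance and their interaction, and refers each term's
$H = SS_{\text{term}} / MS_{\text{total}}$ to a chi-square distribution at
the term's degrees of freedom. Computing
$MS_{\text{total}} = SS_{\text{total}}/(N-1)$ from the empirical rank
variance applies the conventional tie correction implicitly: tied ranks
shrink $SS_{\text{total}}$ by exactly the correction factor. With one
factor collapsed to a single level the statistic reduces to the
tie-corrected Kruskal–Wallis $H$, an identity the tests check against
`stats::kruskal.test()`.

Design choices:

- **Sums of squares.** Balanced designs (the task's case) use the exact
  closed-form decomposition from cell and margin means; unbalanced tables
  fall back to sequential (Type-I) SS with terms ordered modality,
  distance, interaction. The choice is inert for balanced data and
  documented for real, possibly unbalanced, datasets.
- **Two-stage logic.** Stage 1 always fits the interaction. Per response:
  interaction p ≥ α → stage 2 is the interaction-free SRH; interaction
  p < α → stage 2 is two Kruskal–Wallis tests over distance, one per
  modality subset (modality is fixed to keep the number of follow-up tests
  small). α defaults to 0.05 and is configurable. Exactly one stage-2
  outcome exists per response.
- **Rank tests and interactions.** A monotone-separable interaction
  (e.g. multiplicative effects) can be removed by the rank transform and is
  structurally invisible to SRH; only crossing ("non-removable")
  interactions are reliably detected. The branch-reliability tests use a
  crossing interaction for exactly this reason, and users should interpret
  a non-significant SRH interaction accordingly.
- **Spread tests.** Brown–Forsythe (one-way ANOVA F on absolute deviations
  from group medians) for k-group spread; a two-sample variance F test,
  two-sided by default (sidedness is configurable), for the per-distance
  modality comparisons. No multiple-testing correction is applied across
  the seven per-distance tests, mirroring common practice for this design;
  the p-values are reported individually so any correction can be applied
  downstream.
- **Degenerate inputs.** All-tied responses yield H = 0, p = 1 with a
  degeneracy flag rather than an error; a factor with a single level
  degrades to the one-factor test with a warning.

## The synthetic cohort generator

Because trial data of this kind is rarely public, the generator is a
first-class module: every pipeline stage is exercised against cohorts with
known ground truth. A session is 7 targets at 12.5–87.5% of workspace
width × 5 analysis blocks per participant and modality (35 trials), 60 Hz,
10 s trial windows, and a target half-width of 3.6% — a 2.5 cm target
radius on a 27-inch (68.6 cm) workspace.

Each trial is assembled as: a flat reaction-delay segment
(Normal, floored at 0); a sampled minimum-jerk movement from 0 to the drawn
endpoint; a hold at the endpoint to the end of the window. Three design
decisions matter:

- **The duration law is expressed in time-to-target units.** The
  observable the pipeline measures is the time from onset to the 95%
  crossing, which for a movement landing on the target centre is the
  fraction `mjt_crossing_fraction(0.95) ≈ 0.81` of the full minimum-jerk
  duration. The generator draws the *time to target* as
  `intercept + slope × distance + jitter` and derives the MJT duration by
  inverting the crossing fraction for the trial's actual endpoint. This
  makes the generator's slope parameter directly comparable to measured
  time-to-target regressions (the quantity such studies report), and makes
  slope recovery well-posed — parameterising the full duration instead
  would build in a ~19% shrink between parameter and measurement.
- **Noise is signal-dependent.** Zero-mean white noise is
  moving-average-filtered (window 9 samples ≈ 150 ms correlation time),
  rescaled to unit SD, multiplied by the nominal noise SD, and shaped by
  the normalised minimum-jerk speed profile $16\tau^2(1-\tau)^2$. Motor
  noise grows with command magnitude, so the envelope peaks at
  mid-movement — where the local SD equals the nominal value — and vanishes
  at both segment ends, preserving clean rest and hold phases and keeping
  onset detection meaningful.
- **Endpoint scatter is truncated at the target half-width**, so simulated
  subjects always settle within the target band; near-edge settles
  reproduce the >100% path-efficiency phenomenon.

Default noise models (chosen once, from the regularities such tasks
report, before any acceptance run): the manipulandum-like modality is
slower but precise — time to target 0.45 s + 0.01 s/% (far/near ratio
≈ 2.3×), trial-to-trial jitter SD 0.08 s, trajectory noise SD 1.5% (the
reported trace-SD range for arm reaching is roughly 0.5–2.4%), endpoint SD
0.5%, reaction delay 0.15 ± 0.05 s. The sonomyography-like modality is
faster but noisier — 0.35 s + 0.005 s/% (ratio ≈ 1.9×), jitter SD 0.18 s,
trajectory noise SD 5% (reported range roughly 4.3–5.8%), endpoint SD
1.2%, delay 0.20 ± 0.08 s. These produce higher peak velocities and larger
variance for the sonomyography-like modality at every distance, completion
within 2 s for ~95% of its trials (~98% for the manipulandum), and mean
path efficiencies near 98% vs 77%.

What the generator does *not* emulate: corrective submovements and
overshoots (real traces show occasional terminal adjustments; an optional
overshoot mode was considered and deferred), learning across blocks,
subject-level random effects (all subjects share one noise model, so
between-subject variance is underrepresented), and any modality-specific
signal-extraction artefacts. Passing tests therefore validate the
*pipeline* — segmentation, metrics, statistics — under realistic
signal-dependent noise; they do not certify performance on pathologies the
generator lacks.

## Parameter recovery

Two recovery checks tie the pipeline to the generator's ground truth:

- **Time-to-target slope**: OLS of measured time to target on distance
  recovers the generator's slope within 3 standard errors per modality, on
  a default 10-subject cohort (700 trials). Residual bias comes from
  noise-induced early threshold crossings (first-passage advance ~σ/v),
  which the signal-dependent envelope keeps small relative to the SE.
- **Trajectory-noise SD**: from ~400 trials at one distance, each trial's
  minimum-jerk duration is fitted by least squares (endpoint and onset
  fixed by the trace), residuals are scaled by the envelope RMS
  $\sqrt{256\,B(5,5)} \approx 0.637$, and a finite-sample factor
  $n_{\text{eff}}/(n_{\text{eff}}-1)$ with
  $n_{\text{eff}} = n/\text{noise window}$ compensates the variance the
  fitted duration absorbs from correlated noise. Recovery is within a few
  percent of the nominal SD (tolerance 15%).

## Numerical and reproducibility choices

- Calibration of the SRH type-I error uses 10⁴ simulated 2×7 tables with 5
  observations per cell; per-term rejection at α = 0.05 falls in
  [0.035, 0.065] (slightly conservative for the interaction, as expected of
  the chi-square reference at these cell sizes). This and the default
  700-trial cohort keep the full test suite under ~1 minute.
- All randomness in a cohort derives from a single `set.seed()` call;
  identical seed and configuration reproduce trials, metrics and report
  files byte-for-byte. Output files deliberately carry no timestamp — the
  run manifest records version, seed, configuration, a content digest and
  trial counts instead — because wall-clock metadata would break
  byte-level reproducibility.
- CSV outputs fix column order and round floats to 10 significant digits;
  the JSON report is schema-versioned.

## Known limitations

- One-dimensional trajectories only; no curvature, submovement
  decomposition, or Fitts'-law throughput modelling.
- The SRH chi-square reference is asymptotic; very small cells deserve a
  permutation check.
- Rank tests cannot see removable interactions (above).
- Incomplete-trial handling assumes the trial window is long enough that
  genuinely completed movements are never censored mid-flight.
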