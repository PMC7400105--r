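---
title: "Drift correction for multi-session electronic-tongue experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drift correction for multi-session electronic-tongue experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etdrift)
```

## The problem

A potentiometric electronic tongue measures a liquid sample with an array of
partially selective sensors (seven channels, `ZZ BA BB CA GA HA JB`, in the
default configuration) and characterizes it by the resulting multivariate
"fingerprint". Sensor readings that should stay constant do not: between
repeats and especially between weekly sessions they drift under the combined
influence of temperature, cross-contamination carried by the sensor head,
and carryover ("memory") of previous samples on the sensor membranes. Drift
ruins exactly the application the instrument is bought for — comparing
measurements taken weeks apart.

`etdrift` implements four drift corrections as fit/apply pairs, the
evaluation protocol used to compare them, and a synthetic generator of
drifting experiments so the whole pipeline is testable without an
instrument.

## Data model

A `measurement_set` indexes readings by `(session, round, sample_id,
sensor)`. A *round* is one complete pass of the autosampler through the
sample set; a *session* is one (typically weekly) experiment, with session 0
the model-building baseline. Raw acquisition traces (120 s per immersion)
are collapsed to their equilibrium value by averaging the final 10 s
(`collapse_trace()`); the first three rounds of each session are routinely
discarded while the sensors equilibrate (`drop_initial_rounds()`, `k = 3`).
Outlier screening (`flag_outliers()`) scores each observation's Euclidean
distance to its (session, class) centroid with a robust z
(`0.6745 (d - median) / MAD`, one-sided, threshold 3.5) and only *flags*:
component correction is sensitive to outliers, so removal stays an explicit
manual decision.

## The four corrections

Let $X$ be the readings of one (session, round) block, one column per
sensor.

**Additive, relative to all samples.** Without disturbances the block mean
of a fixed sample set is constant, so its movement *is* the drift:
$X' = X - \bar{X}$, per sensor and per round. No assumption about the
drift's cause, but every repeat must measure the same sample set in the
same sequence.

**Additive, relative to reference samples.** The same subtraction with the
mean taken over designated reference classes only, freeing the remaining
samples to vary between repeats.

**Multi-sensor linear correction.** Drift may be multiplicative as well as
additive. Per sensor, the later-session reference readings are regressed
onto the base-session ones, $y = m x + b$, and the map applied to every
reading of that session. We regress per-class reference *centroids* (one
point per reference class), not repeat-paired readings: centroids are
invariant to the arbitrary ordering of repeats, and with balanced noiseless
references the two choices coincide. This needs at least two reference
classes, and a sensor whose reference centroids coincide is a hard error —
a zero slope would silently destroy that sensor's information. Fitted per
session, not per round.

**Component correction (CC).** The dominant principal-component loading
$p$ of pooled reference-class readings from a session pair estimates the
drift direction; each targeted reading is corrected by
$x' = x - m \, \big((x - c) \cdot p\big) \, p$ with $c$ the pooled mean.
We center at $c$ before projecting: PCA loadings are defined on centered
data, and the subtraction is unaffected along directions orthogonal to $p$.
The sign of $p$ is fixed so the base-to-later centroid displacement
projects non-negatively; this is purely cosmetic, as the correction is
invariant to the sign. Two variants are dispatched by `correct()`:

* `cc` (classic, $m = 1$): a single component fitted from the first and
  last sessions and removed from *all* data. The corrected data retain no
  information along $p$; as a consequence the session-0 pooled scatter
  becomes rank-deficient and the LDA fit falls back to a ridge (with a
  warning) — expected, not a defect. Fitting one component per week with
  $m = 1$ is also exposed, but it re-corrects session 0 once per week,
  which is precisely the weakness that motivates the modified variant.
* `cc_modified` ($m = 2$): one component per later session, paired with
  session 0, with *twice* the drift score subtracted from the later
  session only. Geometrically a reflection through the mid-hyperplane:
  under pure-translation drift it maps the later reference cluster onto
  the session-0 cluster, leaves session 0 bit-identical, and keeps the
  information along the drift direction.

All corrections are permutation-equivariant in the sensors; the additive
ones remove a global constant shift while the others commute with it (both
directions are asserted in the test suite).

## Evaluation protocol

`threefold_cv()` builds a canonical LDA on session 0 and projects every
later session. LDA is the classic shared-covariance multiclass variant:
canonical axes solve the generalized eigenproblem of between-class versus
pooled within-class scatter, scaled scatter-orthonormal
($W^\top S_W W = I$), at most $\min(K-1, p)$ axes (3 for 4 classes);
classification is by linear discriminant scores with priors proportional
to training counts. Cross-validation is stratified: per class, a seeded
shuffle is dealt round-robin into three folds, so every base-session
observation is held out exactly once; the seed is recorded in the report.
Later sessions are projected and scored by *each* fold's model, and
accuracies, confusion matrices and distances are reported as fold means
with their fold spread — the error bars are cross-validation spread, not
replicate spread (the alternative reading; noted, not implemented).

`relative_centroid_distance()` tracks a target class (the apple-juice
analog) in the 3-dimensional discriminant space: the distance of its
session-$w$ centroid from its session-0 centroid, normalized by the
session-0 distance between the MSG and citric-acid centroids. Supporting
statistics: full sensor-space centroid distances for stated factors such
as temperature (`centroid_distances_sensor_space()`), univariate OLS
trends (`fit_trend()`, with $R^2 = 0$ by convention for a constant
response), and column-centered PCA (`pca_scores()`) for memory-effect
inspection.

## The synthetic generator: a stated world

`simulate_experiment()` draws, per observation of class $c$ in session $w$:

$$x = g_w \mu_c + d_w + \beta\,(T - T_{\mathrm{ref}}) + \varepsilon,\qquad
\varepsilon \sim N(0, \sigma^2 I)$$

followed by cross-contamination (a per-round shrink of $x$ toward the
cleaning-water level by $(1-\rho)^r$, plus a pH track advancing
`ph_increment` per round in contaminated sessions) and first-order memory
carryover along the physical sequence,
$\mathrm{obs}_i = (1-\lambda)\,x_i + \lambda\,\mathrm{obs}_{i-1}$.

Choices and their grounds:

* **Fingerprints**: fixed vectors on a 800–1500-unit base with pairwise
  class separations of 20–50 units at $\sigma = 1$ — well above the
  10-$\sigma$ separability floor, with the citric-acid and apple-juice
  analogs deliberately the closest pair (they are the chemically closest
  pair, which is also why citric acid is the default CC reference).
* **Sessions/rounds**: 6 sessions of 18 usable rounds of 4 classes. The
  original experiments never state repeats per week explicitly; 18 is
  inferred from the 1/18-step quantization of reported accuracies and is
  a default, not a fact.
* **Additive drift**: a between-session random walk (step norm
  `drift_step`, default 5 units), matching the weekly granularity of the
  protocol; no within-session drift term.
* **Temperature**: linear per sensor, $\|\beta\| = 50$ units/°C — the
  magnitude of the observed distance-versus-temperature slope; the
  concentration direction in the `temperature_sweep` scenario shifts the
  fingerprint by 7 units per percent, again matching the observed order.
* **Carryover**: first-order exponential is the *minimal* mechanism
  reproducing order dependence; no quantitative magnitude is reported
  anywhere, so the defaults ($\lambda = 0.05$ baseline, $0.3$ in
  `memory_orders`) are chosen for testability, not fidelity.
* **Contamination**: deterministic dilution plus a linear pH track
  (0.1/round), consistent with the observed linear pH rise.

The generator emulates additive/multiplicative weekly drift, a linear
temperature response, carryover and dilution. It does **not** emulate
nonlinear sensor response, adsorption/desorption kinetics, electrode
ageing, or session-to-session changes in noise structure — so a green test
establishes that a method behaves correctly *under the stated mechanisms*,
not that it will rescue an arbitrary real instrument. Ground truth
(fingerprint plus the identical noise draws) and the pre-carryover signal
are stored alongside, making every disturbance exactly reconstructible;
`recover_parameters()` exploits this (the carryover estimator is exact by
the recursion, the drift estimator deliberately measures the *total*
additive shift including any gain and temperature contribution).

One evaluation-facing choice: the "large drift" comparison scenario uses
`drift_step = 10` (per-step norm comparable to the smallest class
separation) because its purpose is a regime where raw classification
breaks; this was fixed from that stated condition before the comparisons
were run.

## Numerical choices

* Pooled-scatter singularity (duplicated sensors, post-CC data): ridge
  `1e-8 * max eigenvalue` with a warning; `ridge = FALSE` makes it an
  error.
* Axis signs (LDA and PCA): largest-magnitude element positive, for
  deterministic output; all reported quantities are sign-invariant.
* Ties in classification scores break to the first class in sorted label
  order (measure-zero under the continuous model).
* CSV numbers are written with 17 significant digits, so write/read
  round-trips are bit-exact.
* Degenerate inputs fail loudly and early: duplicate cells, incomplete
  blocks, missing references, constant regressors, rank-0 reference pools
  and zero distance normalizers are all hard errors naming the offender.

## Limitations

* Only linear (affine/orthogonal-projection) drift models; no spline or
  QC-RLSC-style smoothers.
* Single-component CC: one drift direction per session pair.
* Evaluation is LDA-only by design; no PLS-DA/QDA/SVM alternatives and no
  permutation-test significance layer.
* The simulator's realism caveats above apply to every simulation-anchored
  result.
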