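---
title: "Simulated arm motion and the perception of limb stiffness: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated arm motion and the perception of limb stiffness: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stiffsim)
```

This vignette documents the scientific choices inside `stiffsim`: the arm
and controller model, the velocity-profile manipulations, the feature
estimators, the synthetic-rater model, and the numerical decisions that a
user changing defaults should understand. Nothing here reports an
empirical number that the test suite or `scripts/acceptance.R` does not
itself compute.

## The simulated arm

The stimulus source is a rigid two-link planar arm, `M(q)q̈ + C(q,q̇)q̇ +
g(q) = τ`, with the Coriolis matrix built from Christoffel symbols (so
`dM/dt − 2C` is skew-symmetric, which the tests verify against a
finite-difference oracle) and gravity acting in the plane of motion. The
anthropometric defaults (`arm_params()`) describe an average adult male's
upper arm and forearm-plus-hand from standard body-segment tables: link
lengths 0.33/0.32 m, masses 2.10/1.65 kg, centre-of-mass offsets
0.144/0.218 m, moments of inertia 0.024/0.037 kg·m². They are defaults,
not fitted values; every field is configurable, and the timing results
below shift by a few percent under plausible alternative tables.

The controller (`controller_params()`) composes two impedance primitives:
an oscillatory attractor in endpoint coordinates (stiffness
`Kx = diag(500, 500)` N/m, damping `Bx = diag(10, 10)` N·s/m, circular
reference of radius 0.1 m and period 3.33 s) and a fixed-point attractor
in joint coordinates (`Kq = diag(0, E)` toward `qr = (π/4, π/4)`). The
elbow stiffness `E` is the only parameter varied across stimuli. No
gravity-compensation term is added: gravity shifts the steady orbit
downward, and the endpoint spring carries that static load.

Two reference-orbit choices deserve comment.

**Orbit frequency.** The angular frequency is `2π/3.33` rad/s, i.e. one
reference revolution per 3.33 s cycle. This is corroborated by two
independent design anchors: the stated cycle period and the fact that the
constant-condition speed, 0.185 m/s, times 3.33 s recovers the
circumference of a 0.1 m circle to within a few percent.

**Orbit centre.** A circle centred on the shoulder would be unreachable,
so the orbit must be offset; the offset is a genuinely free parameter and
the package treats it as a calibrated one. The default,
`(0.255, 0.255)` m (0.36 m from the shoulder along the 45° ray toward the
`qr` workspace region), was chosen — once — against three structural
anchors of the stimulus set: (1) constant-speed traversal durations of
the steady paths must grow from ≈3.33 s at `E = 0` to ≈3.68 s at
`E = 50`; (2) the spacing between consecutive path centroids must shrink
monotonically along the stiffness ladder; (3) elbow range of motion must
fall monotonically in `E`. The mechanism behind (1) is geometric: a stiff
elbow confines the endpoint to an arc about the shoulder, and the sweep
of that arc — hence the path length — grows as the reference circle
subtends a larger angle at the shoulder. Centres much farther out (e.g.
0.45 m) reverse the duration trend, producing `E = 50` paths *shorter*
than the `E = 0` circle; the default keeps all three anchors satisfied
simultaneously. The acceptance script recomputes the two durations from
scratch at every run.

**Integration.** The state equations are integrated with an adaptive
Dormand–Prince Runge–Kutta scheme (`deSolve::ode`, method `"ode45"`,
`rtol = 1e-8`, `atol = 1e-10`), with dense output resampled to a 1 ms
grid. The simulation starts from rest at the elbow-up
inverse-kinematics solution on the reference circle (ties broken toward
positive elbow angle) and discards transient cycles until the maximum
endpoint distance between corresponding samples of consecutive cycles
falls below 0.1 mm; with the default impedances this takes 2–4 cycles.
One period, inclusive of its closing sample, is returned. Tests verify
that the returned orbit is insensitive to five additional discard cycles
and that a work–energy audit over the cycle (kinetic + spring +
gravitational energy against damping dissipation and the power injected
through the moving reference) closes to well under 0.5% of the dissipated
energy.

## Velocity-profile conditions

Retiming assigns a new time vector to an existing path; positions are
copied bit-for-bit, which makes "path features are invariant across
conditions" a structural property rather than a numerical coincidence.

* **constant** — `t_new = s/v` with `v = 0.185` m/s.
* **inverse** — `υ = K R^(−1/3)`. Because total duration is exactly
  `S/K` with `S = ∫R^(1/3) ds`, the gain that matches the target
  duration has a closed form, `K = S/T`; no iterative tuning is needed
  and the per-path period-matching contract (inverse duration = constant
  duration, within 0.1%) holds to machine precision. The target duration
  defaults to that path's constant-condition duration.
* **variable** — the `E = 50` constant-condition time vector transplanted
  by ordinal sample index. All steady cycles live on the shared 1 ms
  grid of the common 3.33 s period, so sample counts always agree. On
  any path other than the donor's, the transplanted clock yields a
  speed–curvature relation that follows no power law.

**Curvature estimation.** `path_geometry()` smooths the coordinates with
a 9-sample moving average, takes five-point centred differences with
respect to sample index (periodic wrap for closed paths), and evaluates
the parameterization-invariant formula `R = |v|³/|v × a|`, capping `R` at
10 m so straight segments are well defined. On analytic circles the
estimator recovers `R` to 0.1% from 500 samples up; on a 2:1 ellipse the
vertex curvature is recovered to 1%. The cap and window are defaults a
user can change; the retiming itself only consumes `R^(1/3)`, which
damps estimator noise further.

## Feature battery

Per stimulus cycle the package computes: centroid, oblongness (ratio of
position-covariance eigenvalues), enclosed area (shoelace), mean
curvature (mean of `1/R`), shoulder/elbow range of motion, relative
phase between the joint oscillations, and time-weighted RMS velocity,
acceleration and jerk in joint (per joint) and endpoint (vector
magnitude) coordinates.

Centroid, covariance and mean curvature are arc-length weighted by
default so they are invariant to how densely the path is sampled in
time; equal-weight covariance is available (`weighted = FALSE`) for
comparison with textbook ellipse values (uniform-angle samples of an
`a:b` ellipse give oblongness `a²/b²`).

Relative phase is the lag of the peak of the circular cross-correlation
of the mean-removed joint angles, converted to an angle in `(−π, π]` and
positive when the elbow lags the shoulder. The lag is found in samples,
not seconds, so the value is a pure joint-path feature and identical
across the four timing conditions of one path; interpolating onto a
uniform grid in `t_new` would instead make it a (slightly)
timing-dependent quantity, which is not what a path-versus-timing
contrast needs. Resolution is `2π/n` (n ≥ 3330 for simulated cycles) and
the estimator tolerates 5% measurement noise to within 0.05 rad in the
tests.

Derivatives for the RMS metrics use second-order central differences on
the possibly nonuniform `t_new` grid with periodic wrap, applied
successively for acceleration and jerk. On sinusoids the three RMS
values match `Aωᵏ/√2` to 1%, and halving the sample spacing moves them
by well under 0.5%.

## Synthetic raters

The generator emulates the experimental design — blocked schedules, five
repetitions, order randomized within block, the velocity-profile
condition assigned between subjects in Experiment 1 (balanced
round-robin) and within subjects in Experiment 2 — and a deliberately
simple response model:

```
latent = intercept + gain · sign · z(feature) + penalty · [condition ≠ original] + noise
rating = quantize( 4 + (1 − ct) · (latent − 4) )
```

The driving feature defaults to *negated elbow range of motion*, a path
cue consistent with path information dominating stiffness judgments; any
feature column (or `E` itself) can be substituted to explore attribute
substitution. The feature is standardized within subject over the
stimuli that subject actually sees, so `gain` is in rating units per SD.
Central tendency is affine shrinkage toward the scale midpoint 4;
quantization snaps to `n_levels` evenly spaced options on `[1, 7]` (the
default 7 gives the integers 1–7), and the quantization-error variance
falls monotonically as the scale is refined from 3 to 15 options, the
classic discrete-scale noise effect. The Experiment 2 `temporal_penalty`
(default 0.8 rating units in the pipeline configuration) raises every
non-veridical profile, reproducing the structure — not the magnitude —
of the finding that veridically timed motion looks least stiff.

Population defaults (`gain = 1.5 ± 0.5` between subjects, `noise_sd =
0.8`, `central_tendency = 0.1`) were chosen once as a plausible
mid-performance population: they yield mean per-subject R² in the broad
range human raters exhibit, with substantial between-subject spread. No
attempt is made to fit these to human data — the generator exists so the
analysis stage can be tested against known ground truth, and passing
tests certify the pipeline, not human behavior. What the generator does
*not* emulate: learning across blocks (none was needed), non-affine
response heuristics, subject dropout, and any coupling between path and
temporal cues within a rater.

One quantitative caveat the tests respect: quantization of a
noise-dithered latent attenuates recovered slopes by a fraction of a
percent (the rounding transfer-function ripple, `~e^(−2π²σ²)` for noise
SD σ in units of the quantization step). Slope-recovery checks are
therefore run on a heterogeneous population, where the between-subject
standard error — not this ripple — sets the error bar.

## Analysis stage

Per subject, `rating ~ E` is fit by ordinary least squares; slope, R²
and Pearson r are reported, with R² defined as 0 when the rating
variance is zero (degenerate raters). R² equals the squared Pearson
correlation to machine precision, which the tests assert. Group
summaries provide condition means ±2 SE of ratings, R² and slope;
one-way between-subject ANOVAs of R² and slope across conditions
(`aov`); and, for the within-subject design, per-profile means and all
pairwise paired t-tests on per-subject condition means with raw
p-values, as planned comparisons. Repeated-measures ANOVA with
sphericity corrections and binomial regressions on self-reports are
standard off-the-shelf procedures outside this package's bespoke surface.

The strategy coder implements the keyword criteria for the four binary
report features (path, temporal, joint, endpoint information) with
case-insensitive whole-word matching; "angle" deliberately triggers both
the path and joint flags, and picture-based criteria are not codable
from text. A template generator (`generate_strategy_text()`) produces
reports with known flags for coder tests.

## Problem sizes and determinism

The simulated cycles used throughout tests and the acceptance script are
the full-resolution 1 ms grids (3331 samples per cycle; six stiffness
values). Synthetic-rater studies use 8–60 subjects in unit tests and 50
subjects for parameter recovery — enough for stable 2-SE checks while
keeping the whole suite in the minutes range on one CPU. Every stochastic
stage (schedules, rater draws, noise) takes an explicit integer seed and
is reproducible bit-for-bit; the dynamics, retiming and features are
deterministic. A fixed-seed `run_pipeline()` therefore reproduces its
entire report exactly.

## Known limitations

* The reference-orbit centre and the anthropometric table are calibrated
  or borrowed defaults, not measured quantities; timing results carry a
  few percent of sensitivity to them.
* Curvature is estimated, not analytic; paths with near-zero speed or
  cusps would need a different estimator than the smoothed
  cross-product formula.
* The rater model is affine-with-bias by construction. It cannot, and is
  not meant to, adjudicate which heuristic humans actually use; it
  provides ground truth for pipeline validation only.
* Only closed planar paths are supported; there is no 3-D dynamics, no
  muscle model, and no interaction force.
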