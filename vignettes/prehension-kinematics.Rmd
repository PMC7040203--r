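---
title: "Models and methods: reach-to-grasp kinematics in prehensr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: reach-to-grasp kinematics in prehensr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prehensr)
```

prehensr analyses seated reach-to-grasp recordings: a hand starts at rest,
reaches ~400 mm to a paper cup at location A, lifts and transports it 400 mm
to location B, and returns. Three fingertip markers (thumb, index, middle)
are tracked in 3-D at 100 Hz. From these the package extracts the temporal
structure of the reach (peak velocity, the *adjustment time* between the
velocity peak and object contact), the grasp preparation (maximum grip
aperture, MGA, and its timing), and the spatial grip placement relative to
the cup's centre of mass (COM). This vignette documents the models, the
defaults, and the reasoning behind the choices that were genuinely open.

## Movement segmentation

The grip centre — the per-frame mean of the three fingertip positions —
drives segmentation. Its speed is the Euclidean norm of the 3-D velocity,
estimated by central differences (forward/backward at the series edges).
Central differences are the standard motion-capture default; no smoothing is
applied unless a low-pass cutoff is configured (a zero-phase 2nd-order
Butterworth on positions, intended for noisy real recordings and off in all
validation runs).

A movement onset is the **first sample** of a run of at least `min_run = 10`
consecutive samples with speed above `velocity_threshold = 30` mm/s; the
offset is the first sample of the subsequent run of 10 consecutive samples
below it. Timestamping the onset at the run's first sample (not its end)
makes `onset + duration` arithmetic exact. Using the grip centre rather than
a single finger is a declared choice: the criterion describes the *hand*
moving, and the centroid is symmetric in the three fingers. Sample indices
are 1-based throughout, the natural convention for R subsetting; all
reported times are in milliseconds and unaffected by the indexing base.

Ties in peak velocity resolve to the earliest sample. Segments whose peak
falls on their first or last sample are retained but flagged `degenerate`;
an adjustment time of 0 is legal. For every reach,
`adjustment_time + (peak_time - onset_time) = duration` holds exactly.

Trials keep their missing-sample masks: runs of at most 5 samples (50 ms)
are linearly interpolated by `fill_gaps()`, longer runs stay invalid, and a
trial whose fingertips retain an unfilled gap *inside a detected movement
span* is excluded rather than imputed — exclusion is recorded in the
dispositions table, mirroring how dropout-heavy recordings are discarded in
practice. For detection itself, untracked samples count as stationary.

## Cup geometry and grip placement

The cup is a conical frustum, 114 mm tall with outer radii 28.5 mm (base)
and 43.5 mm (top), 11 g empty; filled it weighs 252 g. The COM of the empty
cup is the solid-frustum centroid measured from the base,

$$COM = \frac{h\,(r_1^2 + 2 r_1 r_2 + 3 r_2^2)}{4\,(r_1^2 + r_1 r_2 + r_2^2)},$$

which gives 64.8 mm (65 mm to the nearest millimetre). The solid model is
used deliberately even though a cup is a thin shell: the point of the
package is fidelity to the published analysis, and the shell correction is
an explicit non-goal. Outer radii are used for both cup and liquid; wall
thickness is not published.

```{r com}
frustum_centroid(h = 114, r1 = 28.5, r2 = 43.5)
cup_com(cup_spec_filled())
```

For the filled cup the liquid column is itself a frustum truncated at the
liquid height, and the two centroids combine mass-weighted
(`combined_com()`). The liquid height is treated as **data**, defaulting to
82 mm. This deserves a note: if one instead infers the column height from
the liquid mass assuming water density (241 cm^3), the frustum geometry
puts the surface near 60 mm and the combined COM near 39 mm — which
contradicts the published 46 mm. No liquid height is printed, so the
package takes the height that makes the two published formulas reproduce
the published value (82 mm gives 46.2 mm, printing as 46) and documents the
discrepancy instead of silently resolving it.

The grip centre's vertical position at the contact instant — defined as the
reach offset sample, the only definition consistent with the segmentation
criterion — is compared against `base_z + COM`: deviations above the COM
are positive, below negative. No imputation is permitted at the contact
sample; an invalid fingertip there excludes the trial. The MGA uses the
thumb–index distance only; the middle finger enters only the grip centre.

## The synthetic trial generator

No recordings are deposited, so the generator is a first-class module with
known ground truth for every downstream feature.

**Path model.** Each movement's grip-centre path is a *two-piece
minimum-jerk* profile: an accelerating half-profile of duration $t_a$ and a
decelerating half of duration $t_d$, joined at the common speed peak so
velocity is continuous and terminal speed is zero. For any such path the
peak speed is $1.875\,D/(t_a+t_d)$ regardless of the asymmetry, and the
deceleration piece occupies $t_d$ of the movement — so condition effects on
the adjustment time are injected by stretching $t_d$ alone. A symmetric
split reproduces the classical minimum-jerk bell exactly.

**Calibration to measured quantities.** The condition targets are defined
as the quantities the 30 mm/s criterion *measures*, because the published
means are themselves measured under that criterion. The speed within each
half is $v_p\,16\tau^2(1-\tau)^2$, so the threshold crossings have the
closed form $4\tau(1-\tau)=\sqrt{r}$ with $r = \mathrm{thr}/v_p$; the
generator inverts this (a fast fixed point) to find the $t_d$ whose
expected measured adjustment time equals the target. Defaults inject the
study conditions: adjustment 881/1024 ms and transport peaks 834.01/657.46
mm/s for empty/filled cups, MGA 119.61 mm peaking at 66.78%/61.67% of the
measured reach span, grip deviations ±8.285 mm about the respective COM
(a content effect of −16.57 mm, positive for empty and negative for filled
cups), with surface and feedback null by default as the overall analyses
found them.

**A structural limitation worth knowing.** The minimum-jerk family ties
peak speed to amplitude and duration. With a 400 mm reach and adjustment
times around a second, the implied reach peak is ~450–550 mm/s; the
published reach peaks (~1000 mm/s) cannot coexist with those durations in
this family, because real reaches hover near the cup at low speed in a way
a single smooth profile does not capture. The generator therefore
reproduces the *structure the analyses test* — adjustment-time, transport
peak, MGA-timing and deviation effects — not the absolute reach peak. Reach
peak velocity is consequently not a calibrated quantity of the generator.

**Aperture.** The thumb and index sit half an aperture either side of the
grip centre along a horizontal transverse axis. The aperture rises from
40 mm to the MGA and closes to 70 mm (the cup's girth at grip height) by
contact, using raised-cosine easing. Raised cosine rather than minimum-jerk
easing is deliberate: both are C¹ at the joins, but the minimum-jerk
polynomial is cubically flat at its extremum, which lets millimetre-scale
marker noise wander the argmax asymmetrically and attenuate injected
MGA-timing effects by ~8%; the raised cosine's quadratic peak keeps the
maximum identifiable (residual attenuation under 5%).

**Noise and dropouts.** Gaussian marker noise of 0.15 mm per coordinate
reflects Qualisys-grade optical tracking after labelling. Dropouts are
simulated as contiguous runs (geometric lengths) because occlusions are
bursts, not i.i.d. losses; the default rate is 0 — the dropout machinery is
exercised by dedicated tests, while default datasets are fully analysable.
Between-subject variation enters as random intercepts on each target
(defaults: 100 ms adjustment, 60 mm/s transport peak, 4 points MGA timing,
3 mm deviation, 9 mm MGA), with trial-level jitter (120 ms, 90 mm/s, 5
points, 4 mm, 9 mm) partitioning the published SDs into plausible
within/between components; the published tables give marginal SDs only, so
this partition is a documented free choice.

What the generator does **not** emulate: curved transport paths, hand
tremor and micro-corrections, marker occlusion structure tied to hand
orientation, within-trial correlation between aperture and speed, and
learning across blocks. Passing recovery tests therefore show the pipeline
is unbiased for data satisfying the stated generative assumptions, not that
it is robust to everything real hands do.

## Statistical battery

* `rm_anova()` aggregates to subject × cell means and fits the fully
  within-subject ANOVA via `stats::aov` error strata. Generalized eta
  squared is computed as $SS_e / (SS_e + \sum SS_{error})$ with the sum
  over all error strata including the between-subject stratum — the form
  appropriate when subjects are the only measured factor. No sphericity
  correction is applied by default (two-level factors make it moot for the
  main effects).
* `lmm_fit()` wraps lme4: coefficients and SEs from the REML fit, per-term
  χ² from maximum-likelihood likelihood-ratio tests of nested models,
  matching the χ²(1) reporting convention. Singular subject variances warn
  rather than fail; the estimates then coincide with OLS.
* `clmm_fit()` is a native proportional-odds mixed model: logit link,
  participant random intercept, marginal likelihood by adaptive
  Gauss–Hermite quadrature (21 nodes by default; the per-subject integrand
  is log-concave, so the conditional modes are found by a safe Newton
  iteration and the quadrature is centred and scaled there). Thresholds are
  parameterised by log-differences, hence strictly increasing by
  construction. `sigma_fixed = 0` runs the identical code path with the
  random effect removed — the exact σ→0 limit, which reproduces a plain
  cumulative-link fit and anchors the validation against `MASS::polr`
  (and, after collapsing to two categories, `lme4::glmer`). The freely
  estimated σ is a boundary MLE: on data generated with zero subject
  variance it lands slightly above zero about half the time, which is a
  property of the estimator, not a defect of the quadrature.
* `kruskal_wallis()` wraps `stats::kruskal.test` (tie-corrected H) for the
  block-wise distribution comparisons; all-tied input is flagged degenerate.

No multiple-testing correction is applied, matching the reporting
convention the package mirrors; block-wise analyses are separate fits per
block rather than a block-interaction model.

## Numerical conventions and edge cases

Times are ms, positions mm, speeds mm/s; sampling must be uniform within
1e-6 ms. Measured quantities are quantised to the 10 ms frame: onsets and
offsets land on the first qualifying sample, so recovered times sit within
a frame of the analytic crossing. The `combined_com()` zero-liquid branch
returns the cup centroid *identically* (not via the weighted mean, which
would introduce floating-point noise). The CLMM floors per-observation
category probabilities at 1e-300 to keep extreme linear predictors (the
glossiness-scale effects are near-separating) finite in log-likelihoods.

Validation problem sizes: oracle equivalences run on 200–1000 randomised
cases; parameter-recovery uses 200 replicate datasets at the study design
size (14 participants × 5 blocks × 8 cups); type-I calibration uses 1000
replicate feature tables at a reduced 2-block design via the generator's
feature-level fast path (`simulate_feature_table()`), since those studies
exercise the statistics, not the trajectory layer. These sizes are the
package's validation choices and are stated here so they can be reproduced
or scaled.

## Known limitations

Beyond the generator simplifications above: the automatic segment labeller
is geometric (60 mm landmark radius) and assumes the canonical
start/A/B layout — manual labels override it for unusual sessions; the C3D
reader covers the common Intel-format point-data subset, not analog
channels or events; and the proportional-odds model inherits its usual
assumption that covariate effects are constant across rating thresholds.
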