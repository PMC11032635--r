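---
title: "Conflict-task diffusion models and the midpoint ratio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conflict-task diffusion models and the midpoint ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midpointr)
```

## The scientific problem

Conflict tasks (Eriksen flanker, Stroop, Simon) present a task-relevant
stimulus dimension alongside task-irrelevant information that either primes
the same response (congruent), the opposite response (incongruent), or
neither (neutral). Sequential-sampling accounts of these tasks concentrate on
the congruent/incongruent contrast; the neutral condition is usually treated
as a baseline assumed to fall midway between the two. That *midpoint
assumption* can be written as an equality of mean-RT differences,
`RT_N - RT_C = RT_I - RT_N`, or as a ratio

```
R = (RT_N - RT_C) / (RT_I - RT_N)
```

which equals 1 when the assumption holds. `midpointr` implements the three
dominant conflict-diffusion model families, their deterministic and
stochastic predictions for `R`, two model extensions that relax the midpoint
prediction, and the study-level and subject-level analytics of `R` itself.

## The model families

All three families describe a single relative-evidence accumulator
`X(t)` with time-dependent drift `v(t)`, diffusion coefficient `sigma`,
symmetric absorbing boundaries at `+/- theta_resp` (the `+` boundary is the
correct response), start point 0, and an additive non-decision time `ter`.
Time is in milliseconds throughout; evidence units are arbitrary and
parameter-defined.

**DSTP** (dual-stage two-phase). Phase 1 sums target and flanker evidence,
`v = mu_tar +/- mu_fl` (neutral: flanker weight zero, `v = mu_tar`), while an
independent stimulus-selection diffusion (drift `mu_ss`, thresholds
`+/- theta_sel`) runs in parallel. When selection absorbs, the response drift
switches to `+mu_rs2` (target, or flanker on a congruent trial) or `-mu_rs2`
(flanker on an incongruent trial). A flanker selected on a *neutral* trial
identifies a stimulus that favours neither response; the phase-2 drift is set
to 0 and the trial is flagged, since the original model family leaves this
case unspecified. In the deterministic limit the selection diffusion always
absorbs at the target boundary at `theta_sel / mu_ss`, and the three
conditions' crossing times are piecewise-linear algebra: their spacing is
exactly symmetric, so deterministic DSTP predicts `R = 1` exactly whenever
all three conditions cross in phase 2 (a property the suite checks to the
solver tolerance).

**SSP** (shrinking spotlight). Attention is a centred Gaussian over a
unit-spaced five-item display whose standard deviation shrinks linearly,
`sd_a(t) = max(sd_a - r_d * t, 0)`. The drift weights per-item perceptual
strengths by the spotlight mass over the outer-flanker, inner-flanker and
target regions:

```
v(t) = s * [2 p_outer a_outer(t) + 2 p_inner a_inner(t)] + p_target a_target(t)
```

with flanker sign `s = +1` (congruent), `-1` (incongruent) and, in the
biased-neutral extension, a continuous `bias_b` in `(-1, 1)` for the neutral
condition (`bias_b = 0` is the classic zero-influence neutral). Because the
neutral drift is the pointwise average of the congruent and incongruent
drifts, the deterministic crossing times are near-symmetric: `R = 1` exactly
when all conditions cross after the spotlight has collapsed, and `R`
slightly above 1 otherwise. Deterministic `R` is strictly decreasing in
`bias_b`: a positive bias pulls the neutral toward the congruent RT
(`R < 1`), a negative bias toward the incongruent RT (`R > 1`).

**DMC** (diffusion model of conflict). A controlled process with drift
`mu_c` is superimposed with an automatic process whose expected activation is
a rescaled gamma pulse with amplitude `amp_A`, shape `shape_a > 1` and scale
`tau`; the pulse peaks at exactly `amp_A` at `t = (shape_a - 1) * tau`, adds
on congruent trials, subtracts on incongruent trials, and is absent on
neutral trials. Because the pulse has decayed more by the (later)
incongruent crossing than by the (earlier) congruent crossing, the
incongruent-neutral gap is compressed relative to the congruent-neutral gap
and DMC predicts `R > 1` — *provided the pulse peaks before the controlled
process reaches threshold*. The concave-accrual extension replaces the linear
controlled process with `mu_c(t) = mu_c * exp(-curvature_c * t)`, giving
expected controlled evidence `(mu_c / curvature_c) * (1 - exp(-curvature_c t))`,
bounded above by `mu_c / curvature_c`; `curvature_c = 0` recovers the
published model.

## Parameter presets and unit conventions

Presets (`preset()`, `list_presets()`) carry representative fits from the
model families' original publications, rescaled to the package's
millisecond convention: drift-like rates divided by 1000, the diffusion
coefficient by `sqrt(1000)`; thresholds and the spotlight geometry carry
over unchanged; `theta_resp` is half the boundary separation of the
single-separation convention. The preset file
(`inst/presets/presets.yaml`) documents each source and every field is
overridable. Defaults worth knowing:

* `ssp_flanker`: equal item strength `4e-4`/ms, `sd_a = 1.8`, `r_d = 0.018`/ms
  (spotlight collapses at 100 ms), `theta_resp = 0.05`, `sigma = 3.16e-3`,
  `ter = 300` ms.
* `dmc_flanker` / `dmc_simon`: `amp_A = 20`, `shape_a = 2`, `mu_c = 0.5`,
  `theta_resp = 75`, `sigma = 4`, `ter = 300` ms, with `tau = 100` ms
  (flanker) or 30 ms (Simon).
* `dstp_flanker`: phase-1 drifts of order `1e-4`/ms, `mu_rs2 = 1.43e-3`/ms,
  `theta_resp = 0.059`, `theta_sel = 0.082`, `ter = 322` ms.

## Deterministic predictions

`expected_accumulation()` is closed-form for DMC and DSTP and a composite
trapezoid (0.01 ms step while the spotlight shrinks, exact linear tail
afterwards) for SSP; the suite cross-checks all three against independent
adaptive quadrature of the drift at 1e-6 relative tolerance.
`first_crossing()` scans a 0.1 ms grid for the first sign change of
`E[X(t)] - theta_resp` and refines the first bracketing interval by bisection
to 1e-6 ms; the grid-then-refine design is deliberate because the DMC
incongruent path is non-monotone and can cross late. Crossing is defined
against the correct boundary only; an expected path that dips below
`-theta_resp` first (possible for DMC with a large pulse) triggers a warning
rather than an "error response", because the mean path touching the error
boundary is not a statement about individual trials. `predict_R()` assembles
the three times and the ratio; since a common `ter` cancels from numerator
and denominator, times are reported without it unless requested.

## Stochastic simulation

`simulate_trials()` uses Euler–Maruyama first-passage sampling,
`X <- X + v(t) dt + sigma sqrt(dt) Z`, with drift evaluated at step midpoints
(which also keeps DMC away from its `t = 0` singularity), default
`dt = 1` ms, and a 3000 ms censoring horizon at which unabsorbed trials are
returned censored rather than forced. For DSTP the selection diffusion runs
concurrently with the same `sigma` and switches the response drift on
absorption. One seeded generator drives each call; per-condition substreams
are derived deterministically from the seed so any condition can be
regenerated independently. With `sigma = 0` every trial reproduces the
deterministic crossing to within one `dt` (tested). Start-point and
drift-rate variability, present in some published variants, are deliberately
omitted; the parameter objects are the natural extension point.

Two numerical facts the test suite documents: halving `dt` moves mean RTs by
under 2 ms for the SSP and DMC presets but by roughly 4 ms for DSTP (two
coupled diffusions, boundary-overshoot bias in both), and censoring is below
1% for all shipped presets at the default horizon.

## What noise does to the ratio

`simulated_R()` applies the ratio to per-condition *mean correct* RTs and
attaches a nonparametric bootstrap standard error (200 resamples). A finding
the suite computes and that deserves emphasis: although the deterministic
SSP and DSTP predict `R = 1`, conditioning on correct responses under
realistic noise compresses the incongruent-neutral gap more than the
congruent-neutral gap, so the simulated correct-trial ratio sits *above* 1
(about 1.16 for the SSP preset at 2e5 trials per condition, and far above 1
for DSTP, whose phase-1 errors amplify the effect). The ratio approaches the
deterministic 1 from above as `sigma` shrinks. Published simulation work in
this area has reported a mean ratio slightly *below* 1 for the noisy SSP;
across every analysis variant we implemented (correct-only means,
error-inclusive means, per-batch averaged ratios, medians, across-trial
drift variability) we were unable to produce a sub-1 value from the model as
described, and the package reports what it computes.

## Regime choices for the extension properties

Two qualitative claims are tested on explicit parameter grids, and the grids
are chosen to match the claims' domains of validity rather than the full
parameter hypercube:

* *DMC predicts `R > 1`.* This holds when the automatic pulse peaks before
  the controlled process reaches threshold, i.e. `(shape_a - 1) tau` well
  below `theta_resp / mu_c`; with a pulse peaking at or after the crossing
  the inequality can reverse. The 120-point grid
  (`A` 10–30, `tau` 20–50 ms, `shape_a` 2–3, `mu_c` 0.4–0.6, `theta_resp`
  75) stays inside that regime.
* *`R` is non-increasing in `curvature_c`.* The concave controlled process
  saturates at `mu_c / curvature_c`, so the neutral condition only crosses
  at all when `theta_resp` is below that ceiling; the monotonicity grid uses
  `theta_resp = 15` with `mu_c = 0.5` so the whole range `curvature_c` in
  `[0, 0.02]` is admissible. Outside this regime the direction can reverse
  (with a short, early pulse the exponential decay of the pulse ratio
  outruns the slope effect).

## The synthetic experiment generator

`generate_experiment()` emulates a multi-subject conflict experiment by
jittering each subject's response threshold and controlled-drive parameter
(`mu_c`, `p_target` or `mu_tar` by family) with log-normal factors
`exp(N(0, between_subject_sd))` and simulating trials per condition — the
minimal between-subject structure that makes the paired midpoint t-test
nondegenerate, since the underlying studies provide no subject-level
variability model. `generate_midpoint_cohort()` skips the diffusion entirely
and draws per-subject condition means with a known true midpoint gap; it is
the calibration tool for the power of `midpoint_ttest()` (a -30 ms gap with
20 ms between-subject spread is detected at `alpha = .05` in essentially
every cohort of 50). What these generators do *not* emulate: RT-distribution
shape beyond what the diffusion produces, error-RT structure, practice and
sequence effects, and response-key artefacts — so passing tests certify the
pipeline and the models' comparative statics, not distributional realism of
any particular experiment.

## The literature table

The packaged 52-study table (16 flanker, 17 Simon, 19 Stroop) ships as plain
CSV with a recorded content hash; `load_literature_table()` refuses a
modified file. `analyze_study_table()` recomputes `R` from each study's
three printed means, excludes degenerate denominators (`RT_I = RT_N`), and
reports the share of studies with `R < 1` (45/52 = 86.54%) and per-task
medians. Five rows of the source table print a ratio computed from unrounded
means; recomputation from the printed means differs beyond the 3-decimal
convention, and such rows are flagged, never silently corrected. Aggregation
is purely descriptive — no meta-analytic weighting — and the subject-level
inference implemented is the paired two-sided t-test of the neutral mean
against the congruent/incongruent midpoint (`df = n - 1`); the per-study
ANOVAs of the underlying experiments are out of scope. A zero-variance set
of exactly-zero differences returns `t = 0, p = 1` (the assumption holds
trivially); zero variance around a nonzero mean is an error.

## Problem sizes and limitations

The test suite runs the stochastic checks at 2e5 trials per condition for
the SSP headline ratio, 2e4–3e4 for stability and ordering checks, and 500
replicate cohorts for the t-test power calibration; the acceptance script
uses the same sizes. Known limitations: no parameter estimation from
empirical RT distributions (the package predicts and simulates; it does not
fit), no analytic first-passage-time densities (distributions come from
Monte Carlo), no delta-plot/CAF analytics, and the millisecond rescaling of
published seconds-based parameters is a documented convention, not a claim
that any specific published figure is reproduced at its exact parameter
values (those values are largely unprinted).
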