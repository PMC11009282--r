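---
title: "Joint tuning models for reach sequences: methods and design notes"
author: "seqReach"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint tuning models for reach sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(seqReach)
```

# The problem

When a primate prepares a two-element reaching sequence, motor-cortical
neurons fire differently than for the matching single reach, even though
the first arm movement is kinematically identical. Two hypotheses compete
for what that difference encodes. Under *parallel* coding, the upcoming
second reach is planned independently and its directional tuning simply
adds to the tuning for the first reach. Under *joint* coding, the second
reach acts like a gain field that multiplies the first-reach tuning. The
two hypotheses leave different fingerprints in single-neuron tuning
curves, in the geometry of preparatory population states, and in what a
fixed linear readout (a population vector) reports during the sequence.

This package implements the full analysis chain on synthetic data with
known ground truth: a task/surrogate generator, PSTH and binning
utilities, the joint tuning regressions with permutation chance levels, a
PCA-LDA-QR state-space analysis with sliding-window decoding, the
population-vector simulation, and a continuous-time recurrent network
trained to produce population vectors for the 36-condition task.

# Task geometry

The standard task crosses three trial types (single reach SR, double
reach with the second target displaced 120 degrees clockwise or
counterclockwise) with six first-reach directions on a regular hexagon:
18 conditions. The multi-angle variant allows displacements of +/-60,
+/-120 and 180 degrees: 36 conditions (6 SR + 30 DR). Angles are degrees
throughout, trigonometry is done in radians internally, and returned
angles are normalised to [0, 360).

Two coordinate frames matter for the second reach: the *visual* direction
`theta2` of the second target from the center, and the *execution*
direction `theta21` of the movement from the first target to the second.
Because both targets sit on a circle around the start point, `theta21` is
the chord direction, computed by explicit 2-D vector arithmetic
(`theta21FromTargets()`). All joint models regress on execution
coordinates.

Event markers per trial are target onset (TO), GO, first movement onset
(MO) and end (ME), and for double reaches the second movement onset (MO2)
and end (ME2). Default timing distributions: 400 ms cue, uniform
400-800 ms memory, reaction 250 +/- 40 ms, reach 250 +/- 30 ms, dwell
194 +/- 75 ms (all truncated to keep markers ordered). These are
generator parameters for synthetic trials, not claims about any
particular dataset.

# The tuning models

With `c1 = cos(theta1 - thetaPD)` and `c2 = cos(theta21 - thetaPD)`, the
fitted models are

* single cosine: `FR = a1*c1 + c` (3 parameters),
* additive: `FR = a1*c1 + a2*c2 + c` (4),
* multiplicative: `FR = a1*c1 + b*c1*c2 + c` (4),
* full: `FR = a1*c1 + a2*c2 + b*c1*c2 + c` (5),

with a single intrinsic preferred direction `thetaPD` shared by all terms
of a fit. The parameter count includes `thetaPD`, and model comparison
uses the adjusted R-squared
`1 - ((n-1)/(n-p)) * SSE/SST` so models with different `p` are
comparable.

The multiplicative term has a diagnostic signature: by the product-to-sum
identity,

```
b*cos(theta1 - PD)*cos(theta21 - PD)
  = b/2 * cos(theta21 - theta1) + b/2 * cos(theta1 + theta21 - 2*PD)
```

a sweep of `theta1` at fixed displacement `theta21 - theta1` contains a
second harmonic of amplitude `b/2` ("frequency doubling"), which a purely
additive tuning curve cannot produce. `fourierTuningCurve()` measures
this directly and `productToSumCheck()` exposes both sides of the
identity.

## Fitting: PD-profile engine

At fixed `thetaPD` every model is linear in its coefficients, so the fit
profiles `thetaPD` over a 1-degree grid, solves ordinary least squares at
each grid point (QR decomposition, shared across all series being fitted,
so whole populations and permutation batches are fitted in one pass), and
refines the best grid point by golden-section search. This is convex in
the coefficients given the PD, immune to the local minima of generic
nonlinear least squares, and bitwise reproducible.

The sign ambiguity — flipping `thetaPD` by 180 degrees while negating
`a1` and `a2` leaves predictions unchanged (`b` and `c` are invariant) —
is canonicalised to `a1 >= 0` (then `a2 >= 0`, then `thetaPD` in
[0, 180) on residual ties), which is also why population summaries use
absolute coefficient magnitudes.

In the standard task the single displacement magnitude makes the full
model's `a2` and `b` columns nearly collinear; fits still proceed but
carry an `"aliased"` flag (design condition number above 1e6). The
multi-angle variant is the default for recovery tests for exactly this
reason. Degenerate inputs are flagged rather than fatal: constant
responses report zero coefficients with `r2 = 0` and a `"constant"`
flag.

## Chance levels and population comparison

Permutation chance bands (`permutationCoefficientChance()`) shuffle
condition labels across condition-averaged responses, refit the full
model, and summarise the population-mean absolute coefficients over
(by default) 1000 permutations per bin; the recorded band is the 2.5-97.5
percentile range plus the permutation mean. Model comparison across a
population (`compareModelsPopulation()`) uses the two-tailed Wilcoxon
signed-rank test on paired per-neuron adjusted R-squared per bin, with
effect size `r = |Z|/sqrt(n)` (Z from the tie-corrected normal
approximation, n = number of pairs) and a winner flag at p < 0.0005 per
bin, reported without multiplicity correction across bins since the
output is a per-bin trace.

# Surrogate populations

Each surrogate neuron has an intrinsic preferred direction, a response
latency `tau_n ~ Normal(150, 30) ms` relative to movement onset, and a
rate profile that is constant at `phi * b` before `tau_n` and a Gaussian
bump `b * exp(-(t - tau_n - mu0)^2 / (2 sigma^2))` afterwards, with
`sigma = 150 ms`, preparatory amplitude `phi = 0.2` and
`mu0 = sigma * sqrt(-2 log(phi))` chosen so the profile is continuous at
`tau_n`. Additive Gaussian noise (SD 0.01) is drawn per time sample (the
finer-grained of the two plausible conventions). The condition gain `b`
follows the scheme under study:

* cosine: `(1 + c1)/2`,
* additive: `(1 + c1 + c2)/3`,
* multiplicative: `(1 + c1 + c1*c2)/3`.

Additive and multiplicative gains can be negative (range [-1/3, 1]);
they are abstract activations and are deliberately left unrectified on
the analysis path. Only the Poisson spike sampler floors rates at zero,
explicitly. A `full` scheme draws per-neuron ground-truth coefficients
(stored in `neuronMeta` for recovery tests) and supports scripted
coefficient schedules to emulate a coding transition over time.

What the generator does *not* emulate: spike-count variability tied to
rate (unless the Poisson sampler is used), rate nonstationarities beyond
the single bump, correlated noise across neurons, kinematic variables, or
neuron-to-neuron heterogeneity in `sigma`/`phi`. Passing tests therefore
demonstrate correctness of the analysis chain under the stated model, not
fidelity to any particular recording; monkey-specific percentages,
explained variances and decoding accuracies are intentionally out of
scope.

# State-space analysis

Rates are z-scored per neuron (zero-variance neurons are excluded with a
message), each trial is described by its activity in two 300-ms bins
spanning the 600-ms preparatory window, and the trial-by-feature matrix
is reduced by PCA. The number of components is chosen by stratified
tenfold cross-validation of an LDA classifier on the scores (ties to the
smallest P, which also regularises). Fisher LDA is solved by symmetric
eigendecomposition of the within/between scatter problem with a relative
ridge of 1e-6; eigenvector and basis signs are fixed deterministically so
repeated fits are identical. The PCA-LDA projection is orthonormalised by
QR, so Euclidean geometry within the (C-1)-dimensional state space is
preserved; explained variance per axis is the variance of projected
training data over total feature variance, sorted decreasingly.

Cluster geometry uses the pooled within-class covariance for Mahalanobis
distances (symmetric and stable at small trial counts; a near-singular
pooled covariance receives a logged ridge). The sliding-window decoder
(300-ms bins, 20-ms step) uses the same PCA+LDA+nearest-centroid
classifier under stratified k-fold cross-validation, with a chance band
from 100 whole-dataset label shuffles (shuffling across folds; the band
is the 2.5-97.5 percentile of shuffled accuracies).

# Population-vector readout

The population vector is the sum of unit vectors along each neuron's
*intrinsic* preferred direction weighted by its raw activation (no
baseline subtraction on the surrogate path; a subtraction flag exists for
real data). The angle is reported as NA — never zero — when the
magnitude is below 1e-6.

For uniformly spaced PDs the analytic expectations are sharp: the
cosine-gain population reads out `theta1` exactly; the multiplicative
cross term integrates to zero against the PD circle, so that population
also reads out `theta1`; the additive population is pulled to the
bisector of the two reach directions (a +60 degree error for a
120-degree counterclockwise second reach). `runPVSimulation()` reproduces
this with 200 neurons, six directions, a fixed +120-degree second reach
applied in execution coordinates, and population vectors every 50 ms
across a 600-ms epoch. Evenly spaced PDs are the default for these
analytic checks; random PDs are available and converge to the same
limits as 1/sqrt(N).

# The recurrent network

Dynamics: `tau * dx/dt = -x + J r + B u`, `tau = 50 ms`, rectified-tanh
rates (`r = 0` for `x < 0`, `tanh(x)` otherwise, so `0 <= r < 1`),
linear readout `z = W r`, `N = 200` nodes, Euler integration with
`dt = 10 ms` from `x(0) = 0`. Initialisation: `J ~ Normal(0, g/sqrt(N))`
with `g = 1.5`; `B` and `W` uniform in `+/- 1e-3 * g/sqrt(N)`.

Inputs are five channels held from target onset to trial end: the
Cartesian coordinates of the two reach directions (zero second channel
for SR) and a go channel that steps at GO; a two-trigger variant pulses
the go channel for 150 ms at GO and again at the first touch. The
desired output is a two-peak population-vector profile assembled from
four sections (GO to MO, MO to first touch, MO2-50 ms to MO2, MO2 to
second touch): each reach contributes an asymmetric Gaussian bump
peaking at 1 at the reach midpoint with flank SD one third of the flank
length, over a 0.05 baseline before GO, then the magnitude is normalised
to a maximum of 1. The direction channel carries `theta1` through the
first touch and switches to `theta21` 50 ms before MO2. Training trials
use one representative timing (GO at 800 ms, 250-ms reaction and
reaches, 190-ms dwell) so all 36 conditions share a time base.

Training minimises the mean squared output error plus `lambda = 0.1`
times the squared firing rate averaged over nodes, time bins and
conditions, by backpropagation through time with Adam over all three
weight matrices, batched across the 36 conditions. The learning rate is
5e-3 with early stopping once validation R-squared reaches 0.95 (checked
every 25 iterations, capped at 600): the task is smooth and
low-dimensional, so an aggressive rate with a convergence-based stop
reaches the target band in well under a hundred iterations for most
seeds, and the stop is evaluated *before* the weight update so the
returned weights match the recorded performance. Integration error is
first order in `dt` (halving the step roughly halves the output
deviation); `dt = 10 ms = tau/5` is a deliberate trade of discretisation
error for training cost, and the same `dt` is used for training and
evaluation so the learned dynamics are self-consistent at that step.

Analysis hooks mirror the neural pipeline: `analyzeNodes()` packages
node activity over the 30 DR conditions as a dataset and reuses the
sliding-window full-model regression verbatim; `coefficientFrechet()`
computes the discrete Frechet distance between coefficient-magnitude
trajectories (each trajectory divided by its own joint maximum when
normalisation is requested); `knockdownExperiment()` lesions ten nodes
per bootstrap — all their connections zeroed — from groups defined by
the full-model multiplicative weight (top decile, bottom decile, or any
activated node) and reports the validation deficit over 100 bootstraps.

# Problem sizes and reproducibility

Every stochastic routine takes an explicit seed and restores the
caller's RNG state. The shipped checks use desk-scale sizes chosen to
exercise the claims without waste: a 10-seed network ensemble (the
ensemble mean R-squared lands near 0.96 with MSE near 0.002, comfortably
inside the target band), 200-neuron population-vector simulations, 100
neurons for recovery and model-selection calibrations, 50 null
populations for the census false-positive rate, 300 permutations for
chance-band coverage on 100 noise bins, and 100 label shuffles for the
decoder band. `scripts/acceptance.R` recomputes all of these from
scratch with a single command-line seed.

# Known limitations

* The generator's simplifications listed above; in particular,
  condition gains are time-invariant apart from the latency-gated bump,
  so coding *transitions* must be scripted explicitly.
* In the standard task the full model is partially aliased by design;
  coefficient trajectories from it should be read with the flag in hand.
* The decoder's permutation band shuffles labels across the whole
  dataset; within-fold shuffling would be slightly more conservative.
* The network reproduces the *coding scheme* of the data, not any
  specific recording: comparisons to monkey-specific coefficient
  trajectories (Frechet distances to real sessions) require data this
  package does not ship.
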