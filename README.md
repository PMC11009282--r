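# seqReach

Joint directional tuning and population readout for reach sequences.

When a monkey prepares a memory-guided *double* reach, motor-cortical
neurons fire differently than for the matching single reach even though
the first movement is identical. `seqReach` implements, on synthetic data
with known ground truth, the analysis chain that distinguishes the two
candidate explanations:

- **parallel (additive) coding** — independent tuning to the two reaches:
  `FR = a1*cos(θ1 − θPD) + a2*cos(θ21 − θPD) + c`
- **joint (multiplicative) coding** — the second reach gain-modulates the
  first-reach tuning:
  `FR = a1*cos(θ1 − θPD) + b*cos(θ21 − θPD)*cos(θ1 − θPD) + c`

plus a single-cosine baseline and a **full model** with both terms. Here
`θ1` is the first-reach direction, `θ21` the second-reach direction in
execution coordinates (from the first target to the second), and `θPD`
the neuron's intrinsic preferred direction, shared across all terms of a
fit. Models are compared by adjusted R²,
`1 − ((n−1)/(n−p))·SSE/SST`, with per-bin Wilcoxon signed-rank tests and
permutation chance bands for the coefficients. The multiplicative term is
diagnosable by frequency doubling: swept in `θ1` at fixed `θ21 − θ1` it
contributes a second harmonic of amplitude `b/2`.

The package covers the whole pipeline:

- `makeTaskConfig()` / `generateTrials()` / `generatePopulationDataset()` —
  the 18-condition standard and 36-condition multi-angle double-reach
  tasks, with surrogate populations (cosine / additive / multiplicative
  gains or full-model ground truth) and Poisson spike sampling;
- `computePSTH()`, `assembleNKT()`, `normalizeForRegression()`,
  `zscorePerNeuron()`, `selectivityCensus()` — rate estimation, sliding
  binning and the sequence-selectivity census;
- `fitDirectionModel()` / `fitJointModel()` /
  `slidingWindowRegression()` / `permutationCoefficientChance()` — the
  tuning regressions (PD profiled on a degree grid, OLS at each grid
  point, golden-section refinement);
- `fitSubspace()` / `projectStates()` / `clusterGeometry()` /
  `slidingWindowDecode()` — PCA-LDA-QR state embedding, Mahalanobis
  cluster geometry and cross-validated decoding with shuffle bands;
- `populationVector()` / `runPVSimulation()` — fixed linear readout and
  the three-scheme comparison;
- `initRNN()` / `trainRNN()` / `analyzeNodes()` /
  `knockdownExperiment()` — a 200-node continuous-time recurrent network
  (`τ·dx/dt = −x + J·r + B·u`, rectified-tanh rates, linear readout)
  trained by backpropagation through time with Adam to emit desired
  population vectors for all 36 conditions;
- `runPipeline()` — end-to-end orchestration with a seeded manifest
  (thin CLI wrapper in `inst/scripts/seqreach.R`).

## Worked example

Fit all three sequence models to a surrogate neuron whose ground truth is
multiplicative-dominant (`a1 = 0.55, a2 = 0.15, b = 0.40, c = 0.25,
θPD = 210°`), then compare population-vector readouts across coding
schemes:

```r
library(seqReach)

cfg <- makeTaskConfig("multi_angle", trialsPerCondition = 10, seed = 1)
truth <- data.frame(a1 = 0.55, a2 = 0.15, b = 0.40, c = 0.25, thetaPD = 210)
nkt <- generatePopulationDataset(1, "full", cfg, seed = 1, truth = truth,
                                 window = c(0, 0), dt = 50, noiseSD = 0.05)
fits <- slidingWindowRegression(nkt, c("additive", "multiplicative", "full"))
fits[, c("model", "a1", "a2", "b", "c", "thetaPD", "r2adj")]
#>            model    a1    a2     b     c thetaPD r2adj
#> 1       additive 0.547 0.145    NA 0.102     211 0.803
#> 3           full 0.547 0.145 0.398 0.250     210 0.998
#> 2 multiplicative 0.439    NA 0.398 0.250     210 0.956
```

The full model recovers the generating coefficients and preferred
direction from 30 noisy double-reach condition means; the additive model,
lacking the gain term, loses ~0.2 of adjusted R².

```r
pv <- runPVSimulation(nNeurons = 200, seed = 1)
aggregate(angleError ~ scheme, data = pv[pv$magnitude > 1e-6, ],
          FUN = function(e) round(mean(e), 2))
#>           scheme angleError
#> 1       additive      59.91
#> 2         cosine      -0.07
#> 3 multiplicative      -0.12
```

With 200 evenly spaced preferred directions and a fixed +120° second
reach, the multiplicative population's vector readout still points at the
first-reach direction (like the single-cosine population), while the
additive population is pulled ~60° toward the bisector of the two
reaches — the analytic limit. This is the computational argument that
gain-like joint coding preserves a fixed linear readout of the ongoing
movement during sequence preparation.

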