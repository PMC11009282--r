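test_that("PSTH conserves spike mass and recovers flat rates", {
  # single spike, one trial: Gaussian bump integrating to one spike
  p <- computePSTH(list(0), alignTimes = 0, window = c(-200, 200),
                   kernelSD = 20)
  expect_equal(sum(p$rate) * 1 / 1000, 1, tolerance = 1e-6)
  expect_equal(p$time[which.max(p$rate)], 0)

  # zero spikes: flat zero with zero SE
  p0 <- computePSTH(list(numeric(0), numeric(0)), alignTimes = c(0, 0))
  expect_true(all(p0$rate == 0) && all(p0$se == 0))
  expect_error(computePSTH(list(), numeric(0)), "no trials")

  # homogeneous Poisson spikes: PSTH close to the true rate everywhere
  set.seed(1)
  times <- seq(0, 1000, by = 1)
  spk <- replicate(200, sampleSpikeTrains(times, rep(20, length(times))),
                   simplify = FALSE)
  p <- computePSTH(spk, alignTimes = rep(0, 200), window = c(100, 900),
                   kernelSD = 20)
  # pointwise deviation over ~20 effectively independent kernel widths:
  # allow 4 theoretical SDs (SD = sqrt(rate * intK2 / nTrials) ~ 1.19)
  sdTheory <- sqrt(20 * 1000 / (2 * sqrt(pi) * 20) / 200)
  expect_true(all(abs(p$rate - 20) < 4 * sdTheory))
  expect_equal(mean(p$rate), 20, tolerance = 0.05)
})

test_that("sliding-window binning has the right centers and means", {
  cfg <- makeTaskConfig("standard", trialsPerCondition = 1, seed = 2)
  trials <- generateTrials(cfg)
  arr <- array(7, c(3, nrow(trials), 61))          # constant rate
  nkt <- new("NKTDataset", rates = arr, binCenters = seq(-600, 600, 20),
             alignment = "MO", trials = trials,
             neuronMeta = data.frame(row.names = 1:3))
  out <- assembleNKT(nkt, binWidth = 200, step = 20, window = c(-300, 300))
  # 600-ms window, 200-ms bins, 20-ms step -> 21 centers
  expect_length(binCenters(out), 21)
  expect_true(all(rates(out) == 7))                 # mean-preserving
  one <- assembleNKT(nkt, binWidth = 200, step = 200, window = c(-100, 100))
  expect_length(binCenters(one), 1)
  expect_error(assembleNKT(nkt, window = c(-700, 0)), "span")
  expect_warning(assembleNKT(nkt, binWidth = 40, step = 100,
                             window = c(-300, 300)), "gaps")
})

test_that("max-normalisation is scale invariant and flags silent neurons", {
  nkt <- noiseNKT(3, 10, sd = 0)
  arr <- rates(nkt)
  arr[1, , ] <- 50 * abs(sin(seq_len(dim(arr)[2] * dim(arr)[3])))
  arr[2, , ] <- 2 * arr[1, , ]
  arr[3, , ] <- 0
  nkt@rates <- arr
  out <- normalizeForRegression(nkt, epsilon = 1e-6)
  expect_equal(max(rates(out)[1, , ]), 1, tolerance = 1e-4)
  # doubling a neuron's rates leaves its normalised output unchanged
  expect_equal(rates(out)[1, , ], rates(out)[2, , ], tolerance = 1e-4)
  expect_true(all(rates(out)[3, , ] == 0))
  expect_true(neuronMeta(out)$allZero[3])
})

test_that("z-scoring hits mean 0 / SD 1 and excludes constant neurons", {
  nkt <- noiseNKT(4, 8, sd = 1, seed = 3)
  arr <- rates(nkt)
  arr[4, , ] <- 5                                   # constant neuron
  nkt@rates <- arr
  expect_message(z <- zscorePerNeuron(nkt), "zero-variance")
  expect_equal(dim(rates(z))[1], 3)
  expect_equal(attr(z, "excluded"), 4L)
  for (n in 1:3) {
    expect_lt(abs(mean(rates(z)[n, , ])), 1e-12)
    expect_equal(sd(as.vector(rates(z)[n, , ])), 1, tolerance = 1e-12)
  }
  # two-value toy check against hand-computed z-scores
  toy <- noiseNKT(1, 2, sd = 0)
  toy@rates[1, , 1] <- 1
  toy@rates[1, , 2] <- 3
  zt <- zscorePerNeuron(toy)
  v <- as.vector(rates(zt)[1, , ])
  expect_equal(sort(unique(round(v, 10))), c(-1, 1) / sd(c(rep(1, 30), rep(3, 30))) * 1)
  expect_equal(mean(v), 0)
})

test_that("selectivity census separates constructed groups and respects the null", {
  cfg <- makeTaskConfig("standard", trialsPerCondition = 10, seed = 4)
  # constructed separation: DR rates double the SR rates, tiny noise
  trials <- generateTrials(cfg)
  K <- nrow(trials)
  arr <- array(rnorm(20 * K * 6, 0, 0.01), c(20, K, 6))
  base <- matrix(runif(20, 1, 2), 20, K)
  gain <- ifelse(trials$type == "DR", 2, 1)
  for (t in 1:6) arr[, , t] <- arr[, , t] + base * rep(gain, each = 20)
  nkt <- new("NKTDataset", rates = arr, binCenters = seq(-500, 0, 100),
             alignment = "GO", trials = trials,
             neuronMeta = data.frame(row.names = 1:20))
  cen <- selectivityCensus(nkt, epochSpec("preparatory"), "SR_vs_DR")
  expect_equal(cen$proportion, 1)

  # CW vs CCW with identical distributions: near-alpha false positives
  cen2 <- selectivityCensus(nkt, epochSpec("preparatory"), "CW_vs_CCW")
  expect_lt(cen2$proportion, 0.3)

  # single neuron, equal constant rates in both groups: not significant
  arr1 <- array(1, c(1, K, 6))
  nkt1 <- new("NKTDataset", rates = arr1, binCenters = seq(-500, 0, 100),
              alignment = "GO", trials = trials,
              neuronMeta = data.frame(row.names = 1))
  c1 <- selectivityCensus(nkt1, epochSpec("preparatory"), "SR_vs_DR")
  expect_equal(c1$proportion, 0)
  # epoch anchored to a missing marker errors cleanly
  tr2 <- trials; tr2$GO <- NA
  nkt2 <- new("NKTDataset", rates = arr1, binCenters = seq(-500, 0, 100),
              alignment = "GO", trials = tr2,
              neuronMeta = data.frame(row.names = 1))
  expect_error(selectivityCensus(nkt2, epochSpec("preparatory"),
                                 "SR_vs_DR"), "undefined")
})
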