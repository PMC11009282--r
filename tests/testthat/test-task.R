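test_that("task variants produce the expected condition counts", {
  expect_equal(nrow(makeTaskConfig("standard")$conditions), 18)
  expect_equal(nrow(makeTaskConfig("multi_angle")$conditions), 36)
  cfg <- makeTaskConfig("standard", directions = c(0, 180))
  expect_equal(nrow(cfg$conditions), 6)   # 3 types x 2 directions
  ma <- makeTaskConfig("multi_angle")$conditions
  expect_equal(sum(ma$type == "SR"), 6)
  expect_equal(sum(ma$type == "DR"), 30)
  expect_error(makeTaskConfig("diagonal"), "valid variants")
  expect_error(makeTaskConfig("standard", timing = list(bogus = 1)),
               "bogus")
})

test_that("theta21 equals the chord direction between targets", {
  # independent oracle: explicit 2-D vector arithmetic on the unit circle
  chord <- function(t1, t2) {
    p1 <- c(cos(t1 * pi / 180), sin(t1 * pi / 180))
    p2 <- c(cos(t2 * pi / 180), sin(t2 * pi / 180))
    d <- p2 - p1
    (atan2(d[2], d[1]) * 180 / pi) %% 360
  }
  expect_equal(theta21FromTargets(0, 120), 150)
  expect_equal(theta21FromTargets(0, 240), 210)
  expect_equal(theta21FromTargets(90, 270), 270)  # diametric chord
  for (t1 in c(0, 33, 90, 200)) for (t2 in c(77, 120, 301)) {
    expect_equal(theta21FromTargets(t1, t2), chord(t1, t2),
                 tolerance = 1e-10)
  }
  expect_error(theta21FromTargets(40, 400), "coincide")
  expect_error(theta21FromTargets(Inf, 0), "finite")
})

test_that("trial tables respect timing distributions and determinism", {
  cfg <- makeTaskConfig("standard", trialsPerCondition = 20, seed = 7)
  tab <- generateTrials(cfg)
  expect_equal(nrow(tab), 360)
  # memory period bounds: cue-to-GO delay spans 800-1200 ms
  expect_true(all(tab$GO - tab$TO >= 800 & tab$GO - tab$TO <= 1200))
  expect_true(all(tab$TO < tab$GO & tab$GO < tab$MO & tab$MO < tab$ME))
  dr <- tab[tab$type == "DR", ]
  expect_true(all(dr$ME <= dr$MO2 & dr$MO2 < dr$ME2))
  expect_true(all(is.na(tab$MO2[tab$type == "SR"])))
  expect_true(all(is.na(tab$theta21[tab$type == "SR"])))
  expect_identical(tab, generateTrials(cfg))   # same seed, same table
  expect_error(generateTrials(makeTaskConfig("standard",
                                             trialsPerCondition = 0)),
               "at least 1")
})

test_that("condition gains match the closed forms and stay in range", {
  expect_equal(conditionGain("cosine", 45, NA, 45), 1)
  expect_equal(conditionGain("cosine", 225, NA, 45), 0)
  expect_equal(conditionGain("multiplicative", 10, 10, 10), 1)
  expect_equal(conditionGain("additive", 0, 180, 0), 1 / 3)
  expect_error(conditionGain("quadratic", 0, 0, 0), "unknown scheme")

  grid <- expand.grid(t1 = seq(0, 355, by = 5), t21 = seq(0, 355, by = 5))
  for (sch in c("additive", "multiplicative")) {
    g <- conditionGain(sch, grid$t1, grid$t21, 90)
    expect_true(all(g >= -1 / 3 - 1e-12 & g <= 1 + 1e-12))
  }
  gc <- conditionGain("cosine", grid$t1, NA, 90)
  expect_true(all(gc >= 0 & gc <= 1))

  # rotational equivariance: shifting all angles leaves gains unchanged
  for (delta in c(17, 120, 303)) {
    for (sch in c("cosine", "additive", "multiplicative")) {
      expect_equal(conditionGain(sch, grid$t1 + delta, grid$t21 + delta,
                                 90 + delta),
                   conditionGain(sch, grid$t1, grid$t21, 90),
                   tolerance = 1e-12)
    }
  }
})

test_that("surrogate rate profile is continuous at the latency", {
  # closed form: mu0 = sigma * sqrt(-2 log(phi))
  expect_equal(100 * sqrt(-2 * log(0.2)), 179.4123, tolerance = 1e-4)
  tau <- 150
  left <- simulateRateProfile(tau - 1e-9, gain = 0.8, tau = tau,
                              sigma = 150, noiseSD = 0)
  right <- simulateRateProfile(tau, gain = 0.8, tau = tau, sigma = 150,
                               noiseSD = 0)
  expect_lt(abs(left - right), 1e-12)
  expect_equal(right, 0.2 * 0.8, tolerance = 1e-12)   # phi * b at t = tau
  expect_equal(simulateRateProfile(c(0, 100, 300), gain = 0, tau = tau,
                                   sigma = 150, noiseSD = 0),
               c(0, 0, 0))
  expect_error(simulateRateProfile(0, 1, 100, 100, phi = 0), "phi")
  expect_error(simulateRateProfile(0, 1, 100, sigma = -1), "sigma")
})

test_that("population datasets are reproducible and well-formed", {
  cfg <- makeTaskConfig("standard", trialsPerCondition = 2, seed = 5)
  a <- generatePopulationDataset(8, "multiplicative", cfg, seed = 11)
  b <- generatePopulationDataset(8, "multiplicative", cfg, seed = 11)
  expect_identical(rates(a), rates(b))
  expect_false(anyNA(rates(a)))
  expect_equal(dim(rates(a)), c(8, 36, 13))
  expect_true(validObject(a))
  # ground truth is stored for the full scheme
  tr <- data.frame(a1 = 0.5, a2 = 0.2, b = 0.3, c = 0.1, thetaPD = 40)
  d <- generatePopulationDataset(1, "full", cfg, seed = 1, truth = tr,
                                 noiseSD = 0)
  expect_equal(neuronMeta(d)$b, 0.3)
  expect_error(generatePopulationDataset(2, "full", cfg, truth = tr),
               "one row per neuron")
})

test_that("Poisson spike sampling matches its rate and seed", {
  expect_length(sampleSpikeTrains(c(0, 1000), c(0, 0)), 0)
  times <- seq(0, 1000, by = 1)
  rate <- rep(50, length(times))
  set.seed(42)
  counts <- replicate(500, length(sampleSpikeTrains(times, rate)))
  expect_equal(mean(counts), 50, tolerance = 0.02)  # ~3 SE of the mean
  s1 <- sampleSpikeTrains(times, rate, seed = 9)
  s2 <- sampleSpikeTrains(times, rate, seed = 9)
  expect_identical(s1, s2)
  expect_error(sampleSpikeTrains(times, rate - 100, floorAtZero = FALSE),
               "negative rates")
})
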