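test_that("network initialisation matches its stated distributions", {
  m <- initRNN(seed = 1)
  expect_equal(dim(m@J), c(200, 200))
  expect_equal(sd(as.vector(m@J)), 1.5 / sqrt(200), tolerance = 0.02)
  expect_lt(abs(mean(m@J)), 0.002)
  lim <- 1e-3 * 1.5 / sqrt(200)
  expect_true(all(abs(m@B) <= lim) && all(abs(m@W) <= lim))
  m2 <- initRNN(seed = 1)
  expect_identical(m@J, m2@J)
  expect_false(identical(m@J, initRNN(seed = 2)@J))
})

test_that("trial inputs and targets are assembled as specified", {
  tm <- rnnCanonicalTiming()
  sr <- buildTrialIO(90, NA)
  expect_true(all(sr$u[3:4, ] == 0))            # SR second target = (0, 0)
  expect_equal(max(sqrt(colSums(sr$z^2))), 1, tolerance = 1e-12)
  mag <- sqrt(colSums(sr$z^2))
  # single bump peaking at the grid point nearest mid-reach
  expect_lt(abs(sr$times[which.max(mag)] - (tm$MO + tm$ME) / 2), 10)

  dr <- buildTrialIO(0, 150)
  magd <- sqrt(colSums(dr$z^2))
  # two bumps: high magnitude near each reach midpoint
  i1 <- which.min(abs(dr$times - (tm$MO + tm$ME) / 2))
  i2 <- which.min(abs(dr$times - (tm$MO2 + tm$ME2) / 2))
  expect_gt(magd[i1], 0.95)
  expect_gt(magd[i2], 0.95)
  dip <- which(dr$times > tm$ME & dr$times < tm$MO2 - 50)
  expect_lt(min(magd[dip]), min(magd[i1], magd[i2]))
  # direction switches to theta21 from MO2 - 50 ms
  late <- dr$times >= tm$MO2 - 50
  ang <- atan2(dr$z[2, late], dr$z[1, late]) * 180 / pi
  expect_true(all(abs((ang - 150 + 180) %% 360 - 180) < 1e-9))
  # go channel: step vs double pulse
  expect_equal(unname(sr$u[5, sr$times < tm$GO]),
               rep(0, sum(sr$times < tm$GO)))
  expect_true(all(sr$u[5, sr$times >= tm$GO] == 1))
  tt <- buildTrialIO(0, 150, variant = "two_trigger")
  expect_equal(sum(diff(tt$u[5, ]) == 1), 2)    # pulses twice
  expect_error(buildTrialIO(NA), "invalid condition")
})

test_that("network simulation obeys its dynamical closed forms", {
  m <- initRNN(seed = 3, N = 40)
  Tn <- 100
  io <- list(U = array(0, c(5, Tn, 1)), times = seq(0, 990, by = 10))
  sim <- simulateRNN(m, io)
  # zero input from x(0) = 0 is a fixed point (r(0) = 0)
  expect_true(all(sim$z == 0) && all(sim$rates == 0))

  # J = 0, constant input: x converges to B u0 with time constant tau
  m0 <- m; m0@J <- matrix(0, 40, 40)
  m0@B <- matrix(rnorm(200, 0, 0.5), 40, 5)
  u0 <- c(1, -0.5, 0.3, 0.2, 1)
  io2 <- list(U = array(rep(u0, Tn), c(5, Tn, 1)),
              times = seq(0, 990, by = 10))
  sim2 <- simulateRNN(m0, io2)
  target <- as.vector(m0@B %*% u0)
  atT <- sim2$x[, 1, 26]                       # t = 250 ms = 5 tau
  expect_true(all(abs(atT - target) <= 0.01 * max(abs(target))))

  # rectified-tanh values and bounds
  expect_equal(seqReach:::.rectTanh(-1), 0)
  expect_equal(seqReach:::.rectTanh(1), tanh(1), tolerance = 1e-12)
  expect_true(all(sim2$rates >= 0 & sim2$rates < 1))

  # readout linearity: z of summed rates = sum of z's
  R1 <- matrix(runif(40), 40, 1); R2 <- matrix(runif(40), 40, 1)
  expect_equal(m@W %*% (R1 + R2), m@W %*% R1 + m@W %*% R2,
               tolerance = 1e-12)
  expect_error(simulateRNN(m, io, dt = 40), "tau/2")
})

test_that("training reduces loss reproducibly and regularisation dominates", {
  ts <- buildTrialSet()
  m <- trainRNN(seed = 5, trialSet = ts, N = 60, maxIter = 40,
                stopR2 = 2, checkEvery = 10)
  h <- m@history
  expect_lt(h$mse[nrow(h)], h$mse[1])
  m2 <- trainRNN(seed = 5, trialSet = ts, N = 60, maxIter = 40,
                 stopR2 = 2, checkEvery = 10)
  expect_identical(m@J, m2@J)                  # fixed seed, same weights
  # a huge rate penalty drives activity (and R2) down
  mreg <- trainRNN(seed = 5, trialSet = ts, N = 60, maxIter = 40,
                   stopR2 = 2, lambda = 1e4, checkEvery = 40)
  sim <- simulateRNN(mreg, ts)
  expect_lt(mean(sim$rates^2), 1e-3)
  expect_lt(mreg@history$r2[nrow(mreg@history)], 0.5)
})

test_that("integration converges at first order in the step size", {
  ts10 <- buildTrialSet(dt = 10)
  m <- trainRNN(seed = 6, trialSet = ts10, N = 60, maxIter = 60,
                stopR2 = 2, checkEvery = 20)
  ts5 <- buildTrialSet(dt = 5)
  ts2 <- buildTrialSet(dt = 2.5)
  sub <- function(z, by) z[, seq(1, dim(z)[2], by = by), ]
  z10 <- simulateRNN(m, ts10, dt = 10)$z
  z5 <- sub(simulateRNN(m, ts5, dt = 5)$z, 2)
  z2 <- sub(simulateRNN(m, ts2, dt = 2.5)$z, 4)
  rd <- function(a, b) sqrt(sum((a - b)^2) / max(sum(b^2), 1e-12))
  d1 <- rd(z10, z5)
  d2 <- rd(z5, z2)
  # Euler is first order: halving dt roughly halves the deviation
  expect_lt(d2, d1)
  expect_gt(d1 / d2, 1.5)
  expect_lt(d1 / d2, 3)
})

test_that("discrete Frechet distance has its defining properties", {
  set.seed(7)
  A <- cbind(cumsum(rnorm(30)), cumsum(rnorm(30)), cumsum(rnorm(30)))
  expect_lt(coefficientFrechet(A, A), 1e-6)
  d <- c(0.3, -0.2, 0.5)
  shifted <- sweep(A, 2, d, "+")
  expect_equal(coefficientFrechet(A, shifted), sqrt(sum(d^2)),
               tolerance = 1e-6)
  B <- cbind(cumsum(rnorm(20)), cumsum(rnorm(20)), cumsum(rnorm(20)))
  expect_equal(coefficientFrechet(A, B), coefficientFrechet(B, A))
  expect_error(coefficientFrechet(A[0, ], B), "empty")
})

test_that("knockdown lesions degrade performance as expected", {
  ts <- buildTrialSet()
  m <- trainRNN(seed = 8, trialSet = ts, N = 50, maxIter = 60,
                stopR2 = 2, checkEvery = 20)
  base <- rnnPerformance(m, ts)
  # lesioning every node silences the output: MSE = mean squared target
  mAll <- m
  mAll@J[] <- 0; mAll@B[] <- 0; mAll@W[] <- 0
  pAll <- rnnPerformance(mAll, ts)
  expect_equal(pAll$mse, mean(ts$Z^2), tolerance = 1e-12)
  # bootstrapped knockdown of random nodes: deficits are non-negative-ish
  w <- runif(50)                               # supplied node weights
  kd <- knockdownExperiment(m, "random", nNodes = 5, nBoot = 8, seed = 9,
                            weights = w, trialSet = ts)
  expect_equal(nrow(kd), 8)
  expect_true(all(kd$mse >= 0))
  kd2 <- knockdownExperiment(m, "high", nNodes = 5, nBoot = 8, seed = 9,
                             weights = w, trialSet = ts)
  expect_equal(nrow(kd2), 8)
  expect_error(knockdownExperiment(m, "high", nNodes = 40, nBoot = 2,
                                   weights = w, trialSet = ts), "fewer")
})

test_that("node tuning analysis reuses the joint-model machinery", {
  ts <- buildTrialSet()
  m <- trainRNN(seed = 10, trialSet = ts, N = 50, maxIter = 80,
                stopR2 = 2, checkEvery = 20)
  an <- analyzeNodes(m, ts, bin = 400, step = 400, gridStep = 10)
  expect_true(all(c("a1", "a2", "b") %in% names(an$meanCoefficients)))
  expect_true(all(is.finite(an$meanCoefficients$a1)))
  expect_gt(nrow(an$fits), 0)
})
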