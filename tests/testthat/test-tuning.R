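test_that("single-cosine fits recover exact and degenerate data", {
  th <- seq(0, 300, by = 60)
  y <- 2 + cos((th - 30) * pi / 180)
  f <- fitDirectionModel(y, th)
  expect_equal(f@thetaPD, 30, tolerance = 1e-3)
  expect_equal(f@a1, 1, tolerance = 1e-6)
  expect_equal(f@c, 2, tolerance = 1e-6)
  expect_equal(f@r2, 1, tolerance = 1e-10)
  expect_equal(f@p, 3L)

  fc <- fitDirectionModel(rep(1.5, 6), th)
  expect_equal(fc@a1, 0)
  expect_equal(fc@r2, 0)
  expect_true("constant" %in% fc@flags)
  expect_error(fitDirectionModel(1:3, c(0, 120, 240)), "4 distinct")

  # mis-specified data: R2 must match a brute-force grid oracle
  y2 <- cos(2 * th * pi / 180)
  f2 <- fitDirectionModel(y2, th)
  oracleSSE <- min(sapply(seq(0, 359.5, by = 0.5), function(pd) {
    X <- cbind(cos((th - pd) * pi / 180), 1)
    sum(lm.fit(X, y2)$residuals^2)
  }))
  oracleR2 <- 1 - oracleSSE / sum((y2 - mean(y2))^2)
  expect_equal(f2@r2, oracleR2, tolerance = 1e-6)
})

test_that("joint-model fits recover ground truth from noiseless data", {
  cd <- drConditions()
  y <- jointModelResponse(cd$theta1, cd$theta21, a1 = 0.5, b = 0.3,
                          c = 0.2, thetaPD = 70)
  f <- fitJointModel(y, cd$theta1, cd$theta21, "multiplicative")
  expect_lt(abs(f@thetaPD - 70), 0.5)
  expect_equal(c(f@a1, f@b, f@c), c(0.5, 0.3, 0.2), tolerance = 1e-3)
  expect_equal(f@p, 4L)

  # additive-generated data fitted with the full model: b ~ 0
  ya <- jointModelResponse(cd$theta1, cd$theta21, a1 = 0.6, a2 = 0.4,
                           c = 0.1, thetaPD = 220)
  ff <- fitJointModel(ya, cd$theta1, cd$theta21, "full")
  expect_lt(abs(ff@thetaPD - 220), 0.5)
  expect_equal(c(ff@a1, ff@a2), c(0.6, 0.4), tolerance = 1e-3)
  expect_lt(abs(ff@b), 1e-3)
  expect_equal(ff@p, 5L)

  fz <- fitJointModel(rep(0, nrow(cd)), cd$theta1, cd$theta21, "full")
  expect_true("constant" %in% fz@flags)
  expect_equal(c(fz@a1, fz@a2, fz@b, fz@c), rep(0, 4))
})

test_that("canonicalisation returns a1 >= 0 with unchanged predictions", {
  cd <- drConditions()
  set.seed(8)
  for (i in 1:10) {
    pars <- list(a1 = runif(1, -1, 1), a2 = runif(1, -1, 1),
                 b = runif(1, -1, 1), c = runif(1, -0.5, 0.5),
                 pd = runif(1, 0, 360))
    y <- jointModelResponse(cd$theta1, cd$theta21, pars$a1, pars$a2,
                            pars$b, pars$c, pars$pd)
    f <- fitJointModel(y, cd$theta1, cd$theta21, "full")
    expect_gte(f@a1, 0)
    pred <- jointModelResponse(cd$theta1, cd$theta21, f@a1, f@a2, f@b,
                               f@c, f@thetaPD)
    expect_equal(pred, y, tolerance = 1e-3)
  }
})

test_that("adjusted R2 matches the closed form", {
  expect_equal(adjustedR2(0, 1, 30, 5), 1)
  expect_equal(adjustedR2(0.5, 1, 30, 5), 0.42, tolerance = 1e-12)
  # p = 1: equals plain R2
  expect_equal(adjustedR2(0.3, 1, 12, 1), 1 - 0.3)
  expect_error(adjustedR2(0.1, 1, 5, 5), "exceed")
  expect_error(adjustedR2(0.1, 0, 10, 2), "positive")
})

test_that("product-to-sum identity holds exactly", {
  set.seed(2)
  t1 <- runif(50, 0, 360); t21 <- runif(50, 0, 360)
  ch <- productToSumCheck(t1, t21, thetaPD = 132, b = 0.7)
  expect_equal(ch$lhs, ch$rhs, tolerance = 1e-12)
  # theta1 == theta21: squared cosine, period 180 deg
  ch2 <- productToSumCheck(40, 40, 10, 1)
  expect_equal(ch2$lhs, cos(30 * pi / 180)^2, tolerance = 1e-12)
})

test_that("Fourier tuning curves expose frequency doubling", {
  th <- seq(0, 300, by = 60)
  # pure cosine: all power in harmonic 1
  fc <- fourierTuningCurve(1.2 * cos((th - 45) * pi / 180), th)
  expect_equal(fc$amplitude[fc$harmonic == 1], 1.2, tolerance = 1e-10)
  expect_lt(fc$amplitude[fc$harmonic == 2], 1e-10)
  # constant: harmonic 0 only
  f0 <- fourierTuningCurve(rep(3, 6), th)
  expect_equal(f0$amplitude, c(3, 0, 0), tolerance = 1e-10)
  # multiplicative sweep at fixed theta21 - theta1: second harmonic b/2
  b <- 0.62
  y <- jointModelResponse(th, th + 120, a1 = 0.5, b = b, c = 0.2,
                          thetaPD = 25)
  fm <- fourierTuningCurve(y, th)
  expect_equal(fm$amplitude[fm$harmonic == 2], b / 2, tolerance = 1e-9)
  expect_error(fourierTuningCurve(1:6, c(0, 10, 120, 180, 240, 300)),
               "equally spaced")
})

test_that("model search spaces nest in plain R2", {
  cd <- drConditions()
  set.seed(13)
  for (i in 1:5) {
    y <- rnorm(nrow(cd))
    fits <- lapply(c("cosine_theta1", "additive", "multiplicative", "full"),
                   function(m) fitJointModel(y, cd$theta1, cd$theta21, m,
                                             refine = FALSE))
    r2 <- sapply(fits, function(f) f@r2)
    expect_gte(r2[4] + 1e-10, max(r2[2], r2[3]))
    expect_gte(r2[2] + 1e-10, r2[1])
    expect_gte(r2[3] + 1e-10, r2[1])
  }
})

test_that("population model comparison matches signed-rank arithmetic", {
  # identical fits: p = 1, r = 0
  A <- matrix(runif(40), 20, 2)
  cmp <- compareModelsPopulation(A, A)
  expect_true(all(cmp$p == 1) && all(cmp$effectR == 0))
  expect_true(all(cmp$winner == "none"))

  # all-positive distinct shifts: minimal p for the sample size, A wins
  set.seed(5)
  B <- matrix(runif(60), 30, 2)
  cmp2 <- compareModelsPopulation(B + matrix((1:30) / 100, 30, 2), B,
                                  alpha = 5e-4)
  expect_true(all(cmp2$winner == "A"))
  expect_true(all(cmp2$p < 5e-4))
  # 30 positive differences with distinct ranks: Z at its maximum
  zMax <- (30 * 31 / 4) / sqrt(30 * 31 * 61 / 24)
  expect_equal(cmp2$effectR, rep(zMax / sqrt(30), 2), tolerance = 1e-10)

  # five-pair toy table: statistic matches manual enumeration
  x <- c(2.0, 1.0, 4.0, 5.0, 6.0)
  y <- c(1.0, 3.0, 1.0, 1.0, 1.0)
  # d = 1, -2, 3, 4, 5; ranks of |d| = 1, 2, 3, 4, 5; W+ = 1+3+4+5 = 13
  sr <- seqReach:::.signedRankZ(x, y)
  expect_equal(sr$W, 13)
  expect_equal(sr$Z, (13 - 7.5) / sqrt(5 * 6 * 11 / 24), tolerance = 1e-12)
  expect_error(compareModelsPopulation(A, A[1:10, ]), "paired")
})

test_that("permutation chance bands are seeded and detect real structure", {
  # strongly multiplicative population: observed |b| far above the band
  nkt <- tunedPopulation(15, "multiplicative", noiseSD = 0.02, seed = 2)
  ch <- permutationCoefficientChance(nkt, nPerm = 120, seed = 3,
                                     gridStep = 5)
  bRow <- ch[ch$coefficient == "b", ]
  expect_gt(bRow$observed, bRow$hi)
  ch2 <- permutationCoefficientChance(nkt, nPerm = 120, seed = 3,
                                      gridStep = 5)
  expect_identical(ch, ch2)
  expect_warning(permutationCoefficientChance(nkt, nPerm = 50, seed = 1,
                                              gridStep = 10), "coarse")
})

test_that("sliding-window trajectories track scripted coefficient schedules", {
  # stationary truth: flat trajectories; multiplicative -> additive switch
  cfg <- makeTaskConfig("multi_angle", trialsPerCondition = 1, seed = 6)
  truth <- data.frame(a1 = rep(0.5, 6), a2 = 0.5, b = 0.5, c = 0.3,
                      thetaPD = seq(15, 315, by = 60))
  sched <- function(t) if (t < 0) c(1, 0, 1) else c(1, 1, 0)
  nkt <- generatePopulationDataset(6, "full", cfg, seed = 6, truth = truth,
                                   schedule = sched, window = c(-200, 200),
                                   dt = 50, noiseSD = 0)
  fits <- slidingWindowRegression(nkt, "full", gridStep = 2)
  pre <- fits[fits$binCenter < 0, ]
  post <- fits[fits$binCenter > 0, ]
  expect_gt(mean(abs(pre$b)), 0.4)
  expect_lt(mean(abs(pre$a2)), 0.05)
  expect_gt(mean(abs(post$a2)), 0.4)
  expect_lt(mean(abs(post$b)), 0.05)
  expect_error(slidingWindowRegression(nkt, character(0)), "empty")
})
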