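# Continuous-time recurrent network trained to emit desired population
# vectors for the 36-condition reach-sequence task.
#
# Dynamics (Euler-integrated):  tau * dx/dt = -x + J r + B u,
# rectified-tanh rates r = 0 (x < 0) / tanh(x) (x >= 0), linear readout
# z = W r. Training minimises mean squared output error plus a firing-rate
# penalty, by backpropagation through time with Adam.

.rectTanh <- function(x) ifelse(x < 0, 0, tanh(x))
.rectTanhGrad <- function(x) ifelse(x < 0, 0, 1 - tanh(x)^2)

#' Initialise a recurrent network
#'
#' Internal weights `J` are drawn Normal(0, g/sqrt(N)) (g = 1.5); input
#' weights `B` and readout weights `W` are drawn uniformly in
#' `[-1e-3 * g/sqrt(N), 1e-3 * g/sqrt(N)]`, so the untrained network is
#' input-silent apart from its internal dynamics.
#'
#' @param seed integer seed.
#' @param N number of nodes (default 200).
#' @param nInputs input channels (default 5: cos/sin of the two reach
#'   directions plus a go channel).
#' @param tau time constant in ms (default 50).
#' @param g internal weight scale (default 1.5).
#' @param dt Euler step in ms (default 10; must satisfy `dt <= tau/2`).
#' @return an [RNNModel-class] with empty training history.
#' @export
initRNN <- function(seed = 0L, N = 200L, nInputs = 5L, tau = 50, g = 1.5,
                    dt = 10) {
  rs <- .restoreSeed(seed)
  on.exit(rs())
  sdJ <- g / sqrt(N)
  J <- matrix(stats::rnorm(N * N, 0, sdJ), N, N)
  lim <- 1e-3 * sdJ
  B <- matrix(stats::runif(N * nInputs, -lim, lim), N, nInputs)
  W <- matrix(stats::runif(2 * N, -lim, lim), 2, N)
  new("RNNModel", J = J, B = B, W = W, tau = tau, g = g, dt = dt,
      history = data.frame(iteration = integer(), loss = numeric(),
                           mse = numeric(), r2 = numeric()),
      config = list(seed = as.integer(seed), N = as.integer(N),
                    nInputs = as.integer(nInputs)))
}

#' Canonical trial timing for network training
#'
#' Representative event times (ms) used to build the network's training
#' trials: target onset at 0, a 400-ms cue plus 400-ms memory period to
#' GO, 250-ms reaction and reach times, and a 190-ms dwell on the first
#' target, with a short tail after the second touch.
#'
#' @return named list `TO`, `GO`, `MO`, `ME`, `MO2`, `ME2`, `end`.
#' @export
rnnCanonicalTiming <- function() {
  list(TO = 0, GO = 800, MO = 1050, ME = 1300, MO2 = 1490, ME2 = 1740,
       end = 1840)
}

#' Build network inputs and target outputs for one condition
#'
#' Inputs are five channels held from target onset to trial end: the 2-D
#' Cartesian coordinates of the first reach direction, those of the second
#' reach direction (zero for single-reach trials), and a go channel that
#' steps to 1 at GO (`single_go`) or pulses for 150 ms at GO and again at
#' the first target touch (`two_trigger`).
#'
#' The desired output is a 2-D population vector `m(t) * (cos, sin)` of
#' the ongoing movement direction. Its magnitude is spliced from Gaussian
#' flanks over four sections (GO to MO, MO to first touch, 50 ms before
#' MO2 to MO2, MO2 to second touch): each reach contributes an asymmetric
#' Gaussian bump peaking at 1 at the reach midpoint with flank SD one
#' third of the flank length, over a 0.05 baseline before GO; the maximum
#' magnitude is 1 by construction. The direction channel carries the
#' first-reach direction through the first touch and switches to the
#' second-reach direction 50 ms before MO2.
#'
#' @param theta1 first-reach direction (deg).
#' @param theta21 second-reach direction in execution coordinates (deg),
#'   or NA for a single reach.
#' @param timing event times, see [rnnCanonicalTiming()].
#' @param variant `"single_go"` or `"two_trigger"`.
#' @param dt time step in ms.
#' @param goPulse pulse width in ms for the two-trigger variant.
#' @param baseline pre-GO target magnitude.
#' @return list with `u` (5 x T input matrix), `z` (2 x T target matrix),
#'   `times`, `timing`, `theta1`, `theta21`.
#' @export
buildTrialIO <- function(theta1, theta21 = NA_real_,
                         timing = rnnCanonicalTiming(),
                         variant = c("single_go", "two_trigger"),
                         dt = 10, goPulse = 150, baseline = 0.05) {
  variant <- match.arg(variant)
  if (!is.finite(theta1)) stop("invalid condition: theta1 must be finite")
  isDR <- is.finite(theta21)
  times <- seq(timing$TO, timing$end, by = dt)
  Tn <- length(times)

  u <- matrix(0, 5, Tn)
  u[1, ] <- cosd(theta1)
  u[2, ] <- sind(theta1)
  if (isDR) {
    u[3, ] <- cosd(theta21)
    u[4, ] <- sind(theta21)
  }
  if (variant == "single_go") {
    u[5, times >= timing$GO] <- 1
  } else {
    u[5, times >= timing$GO & times < timing$GO + goPulse] <- 1
    u[5, times >= timing$ME & times < timing$ME + goPulse] <- 1
  }

  asymBump <- function(t, center, sdL, sdR) {
    s <- ifelse(t < center, sdL, sdR)
    exp(-(t - center)^2 / (2 * s^2))
  }
  c1 <- (timing$MO + timing$ME) / 2
  m <- asymBump(times, c1, (c1 - timing$GO) / 3, (timing$ME - c1) / 3)
  if (isDR) {
    c2 <- (timing$MO2 + timing$ME2) / 2
    m2 <- asymBump(times, c2, (c2 - (timing$MO2 - 50)) / 3,
                   (timing$ME2 - c2) / 3)
    m <- pmax(m, m2)
  }
  m[times < timing$GO] <- pmax(m[times < timing$GO], baseline)
  m <- m / max(m)                 # normalise magnitude to a maximum of 1

  theta <- rep(theta1, Tn)
  if (isDR) theta[times >= timing$MO2 - 50] <- theta21
  z <- rbind(m * cosd(theta), m * sind(theta))
  list(u = u, z = z, times = times, timing = timing,
       theta1 = theta1, theta21 = theta21)
}

#' Training/validation trial set for the 36-condition task
#'
#' Builds the inputs and desired outputs for every condition of the
#' multi-angle task (6 single-reach + 30 double-reach conditions).
#'
#' @param variant go-channel variant, see [buildTrialIO()].
#' @param dt time step in ms.
#' @param timing event times.
#' @return list with `U` (5 x T x C input array), `Z` (2 x T x C target
#'   array), `times`, and the `conditions` data.frame.
#' @export
buildTrialSet <- function(variant = "single_go", dt = 10,
                          timing = rnnCanonicalTiming()) {
  conds <- makeTaskConfig("multi_angle")$conditions
  ios <- lapply(seq_len(nrow(conds)), function(i)
    buildTrialIO(conds$theta1[i], conds$theta21[i], timing, variant, dt))
  Tn <- length(ios[[1]]$times)
  C <- length(ios)
  U <- array(0, c(5, Tn, C))
  Z <- array(0, c(2, Tn, C))
  for (i in seq_len(C)) {
    U[, , i] <- ios[[i]]$u
    Z[, , i] <- ios[[i]]$z
  }
  list(U = U, Z = Z, times = ios[[1]]$times, conditions = conds,
       timing = timing)
}

# Batched Euler forward pass.
# U: I x T x C. Returns X, R (N x C x T arrays) and Z (2 x T x C).
.rnnForward <- function(J, B, W, tau, dt, U, keepStates = TRUE) {
  N <- nrow(J)
  I <- dim(U)[1]; Tn <- dim(U)[2]; C <- dim(U)[3]
  a <- dt / tau
  X <- matrix(0, N, C)
  Xs <- if (keepStates) array(0, c(N, C, Tn)) else NULL
  Rs <- if (keepStates) array(0, c(N, C, Tn)) else NULL
  Z <- array(0, c(2, Tn, C))
  for (t in seq_len(Tn)) {
    R <- .rectTanh(X)
    if (keepStates) { Xs[, , t] <- X; Rs[, , t] <- R }
    Z[, t, ] <- W %*% R
    if (t < Tn) {
      Ut <- matrix(U[, t, ], I, C)
      X <- (1 - a) * X + a * (J %*% R + B %*% Ut)
      if (!all(is.finite(X)))
        stop("non-finite network state at step ", t,
             " (max |x| = ", max(abs(X[is.finite(X)]), 0), ")")
    }
  }
  list(X = Xs, R = Rs, Z = Z)
}

#' Simulate a recurrent network
#'
#' Euler-integrates the network dynamics from `x(0) = 0` for one or more
#' trials and returns node activity and outputs.
#'
#' @param model an [RNNModel-class].
#' @param io a trial from [buildTrialIO()] or a trial set from
#'   [buildTrialSet()].
#' @param dt integration step in ms (default the model's own; must be
#'   <= tau/2).
#' @return list with `rates` (N x C x T array of node firing rates),
#'   `x` (N x C x T array of node activations), `z` (2 x T x C outputs),
#'   `times`.
#' @export
simulateRNN <- function(model, io, dt = model@dt) {
  stopifnot(is(model, "RNNModel"))
  if (dt > model@tau / 2) stop("dt must satisfy dt <= tau/2")
  U <- if (!is.null(io$U)) io$U else array(io$u, c(dim(io$u), 1))
  fwd <- .rnnForward(model@J, model@B, model@W, model@tau, dt, U)
  list(rates = fwd$R, x = fwd$X, z = fwd$Z, times = io$times)
}

# MSE and R2 of outputs against targets (arrays 2 x T x C)
.outputPerformance <- function(Z, Ztarget) {
  err <- Z - Ztarget
  mse <- mean(err^2)
  sst <- mean((Ztarget - mean(Ztarget))^2)
  list(mse = mse, r2 = 1 - mse / sst)
}

#' Train a recurrent network on the reach-sequence task
#'
#' Optimises all three weight matrices (J, B, W) by backpropagation
#' through time with Adam. The cost is the mean squared error between the
#' network output and the desired population vector plus a regularity
#' term: the squared firing rate averaged over nodes, time bins and
#' conditions, weighted by `lambda`. Training stops early once the
#' validation R-squared reaches `stopR2`.
#'
#' @param seed integer seed (controls initialisation only; the task set
#'   is deterministic).
#' @param trialSet trial set from [buildTrialSet()] (built on demand if
#'   NULL).
#' @param lambda firing-rate penalty weight (default 0.1).
#' @param lr Adam learning rate (default 5e-3).
#' @param maxIter maximum Adam iterations (default 3000).
#' @param stopR2 early-stopping R-squared (default 0.95; set above 1 to
#'   disable).
#' @param N,tau,g,dt network size and constants, see [initRNN()].
#' @param checkEvery iterations between history records.
#' @param verbose print progress.
#' @return a trained [RNNModel-class]; `@history` holds the loss/MSE/R2
#'   trace and `@config` the training settings.
#' @export
trainRNN <- function(seed = 0L, trialSet = NULL, lambda = 0.1, lr = 5e-3,
                     maxIter = 3000, stopR2 = 0.95, N = 200L, tau = 50,
                     g = 1.5, dt = 10, checkEvery = 10, verbose = FALSE) {
  if (is.null(trialSet)) trialSet <- buildTrialSet(dt = dt)
  U <- trialSet$U; Ztar <- trialSet$Z
  I <- dim(U)[1]; Tn <- dim(U)[2]; C <- dim(U)[3]
  model <- initRNN(seed, N = N, nInputs = I, tau = tau, g = g, dt = dt)
  J <- model@J; B <- model@B; W <- model@W
  a <- dt / tau
  nz <- 2 * Tn * C          # output elements
  nr <- N * Tn * C          # rate elements
  cR <- 2 * lambda / nr

  # flattened-parameter Adam state
  adam <- list(mJ = J * 0, vJ = J * 0, mB = B * 0, vB = B * 0,
               mW = W * 0, vW = W * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  hist <- list()
  Uperm <- aperm(U, c(1, 3, 2))            # I x C x T (C-within-t stacking)
  UstackT <- matrix(Uperm[, , seq_len(Tn - 1)], I, C * (Tn - 1))

  for (it in seq_len(maxIter)) {
    fwd <- .rnnForward(J, B, W, tau, dt, U)
    R <- fwd$R; X <- fwd$X; Z <- fwd$Z
    err <- Z - Ztar                        # 2 x T x C
    mse <- mean(err^2)
    penal <- lambda * mean(R^2)
    loss <- mse + penal

    # record/stop before updating so the returned weights match the
    # last recorded performance
    if (it %% checkEvery == 0 || it == 1 || it == maxIter) {
      perf <- .outputPerformance(Z, Ztar)
      hist[[length(hist) + 1L]] <- data.frame(
        iteration = it, loss = loss, mse = mse, r2 = perf$r2)
      if (verbose)
        message(sprintf("iter %4d  loss %.5f  mse %.5f  R2 %.4f",
                        it, loss, mse, perf$r2))
      if (perf$r2 >= stopR2) break
    }

    E <- aperm(err, c(1, 3, 2)) * (2 / nz) # 2 x C x T
    D <- array(0, c(N, C, Tn))             # dL/dx
    dlt <- matrix(0, N, C)
    for (t in Tn:1) {
      gR <- crossprod(W, matrix(E[, , t], 2, C)) + cR * R[, , t]
      if (t < Tn) gR <- gR + a * crossprod(J, dlt)
      dnew <- .rectTanhGrad(X[, , t]) * gR
      if (t < Tn) dnew <- dnew + (1 - a) * dlt
      D[, , t] <- dnew
      dlt <- dnew
    }
    Dstack <- matrix(D[, , 2:Tn], N, C * (Tn - 1))
    Rstack <- matrix(R[, , seq_len(Tn - 1)], N, C * (Tn - 1))
    gJ <- a * tcrossprod(Dstack, Rstack)
    gB <- a * tcrossprod(Dstack, UstackT)
    # E (2 x C x T) and R (N x C x T) share the C-within-t column order
    gW <- tcrossprod(matrix(E, 2, C * Tn), matrix(R, N, C * Tn))

    step <- function(p, gp, m, v) {
      m <- b1 * m + (1 - b1) * gp
      v <- b2 * v + (1 - b2) * gp^2
      mh <- m / (1 - b1^it); vh <- v / (1 - b2^it)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
    }
    sJ <- step(J, gJ, adam$mJ, adam$vJ); J <- sJ$p; adam$mJ <- sJ$m; adam$vJ <- sJ$v
    sB <- step(B, gB, adam$mB, adam$vB); B <- sB$p; adam$mB <- sB$m; adam$vB <- sB$v
    sW <- step(W, gW, adam$mW, adam$vW); W <- sW$p; adam$mW <- sW$m; adam$vW <- sW$v
  }

  history <- do.call(rbind, hist)
  new("RNNModel", J = J, B = B, W = W, tau = tau, g = g, dt = dt,
      history = history,
      config = list(seed = as.integer(seed), N = as.integer(N),
                    nInputs = I, lambda = lambda, lr = lr,
                    maxIter = maxIter, stopR2 = stopR2,
                    timing = trialSet$timing))
}

#' Validation performance of a network
#'
#' Simulates the network on a trial set and reports output MSE and
#' R-squared against the desired population vectors.
#'
#' @param model an [RNNModel-class].
#' @param trialSet trial set from [buildTrialSet()].
#' @return list with `mse` and `r2`.
#' @export
rnnPerformance <- function(model, trialSet = NULL) {
  if (is.null(trialSet)) trialSet <- buildTrialSet(dt = model@dt)
  fwd <- .rnnForward(model@J, model@B, model@W, model@tau, model@dt,
                     trialSet$U, keepStates = FALSE)
  .outputPerformance(fwd$Z, trialSet$Z)
}

#' Tuning analysis of network nodes
#'
#' Simulates the network over the 30 double-reach conditions, packages
#' node activity as an [NKTDataset-class] (one "trial" per condition),
#' normalises it, and fits the full joint tuning model in sliding windows,
#' exactly as for recorded neurons. Returns the per-node fits and the
#' population-mean absolute coefficient trajectories.
#'
#' @param model a trained [RNNModel-class].
#' @param trialSet trial set from [buildTrialSet()].
#' @param bin,step sliding regression window in ms.
#' @param gridStep PD grid step (deg).
#' @param nodes optional node subset (default all nodes with non-constant
#'   activity).
#' @return list with `fits` (per-node data.frame from
#'   [slidingWindowRegression()]), `meanCoefficients` (data.frame per bin:
#'   mean |a1|, |a2|, |b|), and the `nkt` used.
#' @export
analyzeNodes <- function(model, trialSet = NULL, bin = 200, step = 20,
                         gridStep = 2, nodes = NULL) {
  if (is.null(trialSet)) trialSet <- buildTrialSet(dt = model@dt)
  sim <- simulateRNN(model, trialSet)
  conds <- trialSet$conditions
  isDR <- conds$type == "DR"
  Rarr <- sim$rates[, isDR, , drop = FALSE]     # N x C_DR x T
  if (is.null(nodes)) {
    spread <- apply(Rarr, 1, function(x) max(x) - min(x))
    nodes <- which(spread > 1e-8)
  }
  Rarr <- Rarr[nodes, , , drop = FALSE]
  tr <- conds[isDR, , drop = FALSE]
  tr$trial <- seq_len(nrow(tr))
  tm <- trialSet$timing
  tr$TO <- tm$TO; tr$GO <- tm$GO; tr$MO <- tm$MO; tr$ME <- tm$ME
  tr$MO2 <- tm$MO2; tr$ME2 <- tm$ME2
  nkt <- new("NKTDataset", rates = Rarr, binCenters = trialSet$times,
             alignment = "TO", trials = tr,
             neuronMeta = data.frame(node = nodes))
  nkt <- normalizeForRegression(nkt, epsilon = 0.05)
  fits <- slidingWindowRegression(nkt, "full", bin = bin, step = step,
                                  gridStep = gridStep)
  agg <- stats::aggregate(cbind(a1 = abs(fits$a1), a2 = abs(fits$a2),
                                b = abs(fits$b)),
                          by = list(binCenter = fits$binCenter), FUN = mean)
  list(fits = fits, meanCoefficients = agg, nkt = nkt)
}

#' Discrete Fréchet distance between coefficient trajectories
#'
#' Discrete Fréchet distance between two time-parameterised trajectories
#' (rows = time points, columns = dimensions, e.g. the three coefficient
#' magnitudes |a1|, |a2|, |b|). Use `normalize = TRUE` to divide each
#' trajectory by its joint maximum first, the scaling used when comparing
#' coefficient patterns across datasets.
#'
#' @param trajA,trajB numeric matrices with the same number of columns.
#' @param normalize divide each trajectory by its own joint maximum.
#' @return the discrete Fréchet distance (scalar).
#' @export
coefficientFrechet <- function(trajA, trajB, normalize = FALSE) {
  A <- as.matrix(trajA); B <- as.matrix(trajB)
  if (nrow(A) == 0 || nrow(B) == 0) stop("empty trajectory")
  if (ncol(A) != ncol(B)) stop("trajectories must share dimensions")
  if (normalize) {
    A <- A / max(abs(A))
    B <- B / max(abs(B))
  }
  n <- nrow(A); m <- nrow(B)
  d <- sqrt(pmax(outer(rowSums(A^2), rep(1, m)) +
                 outer(rep(1, n), rowSums(B^2)) - 2 * A %*% t(B), 0))
  ca <- matrix(0, n, m)
  ca[1, 1] <- d[1, 1]
  for (i in 2:max(n, 2)) if (n > 1) ca[i, 1] <- max(ca[i - 1, 1], d[i, 1])
  for (j in 2:max(m, 2)) if (m > 1) ca[1, j] <- max(ca[1, j - 1], d[1, j])
  if (n > 1 && m > 1)
    for (i in 2:n) for (j in 2:m)
      ca[i, j] <- max(min(ca[i - 1, j], ca[i - 1, j - 1], ca[i, j - 1]),
                      d[i, j])
  ca[n, m]
}

#' Node-knockdown perturbation experiment
#'
#' Lesions groups of nodes (all their connections in J, B and W set to
#' zero) and measures the validation performance deficit. Groups are
#' defined by node weight (by default the full-model multiplicative
#' coefficient magnitude from [analyzeNodes()], averaged over bins):
#' `high` = the top decile of activated nodes, `low` = the bottom decile,
#' `random` = any activated node. Each bootstrap randomly selects
#' `nNodes` nodes from the group.
#'
#' @param model a trained [RNNModel-class].
#' @param group `"high"`, `"low"` or `"random"`.
#' @param nNodes nodes lesioned per bootstrap (default 10).
#' @param nBoot bootstrap repetitions (default 100).
#' @param seed integer seed.
#' @param weights optional per-node weights (length N; NA for inactive
#'   nodes); computed via [analyzeNodes()] when missing.
#' @param trialSet validation set from [buildTrialSet()].
#' @return data.frame per bootstrap: `group`, `boot`, `mse`, `r2`,
#'   `deficit` (MSE increase over the intact network).
#' @export
knockdownExperiment <- function(model, group = c("high", "low", "random"),
                                nNodes = 10, nBoot = 100, seed = 1L,
                                weights = NULL, trialSet = NULL) {
  group <- match.arg(group)
  if (is.null(trialSet)) trialSet <- buildTrialSet(dt = model@dt)
  if (is.null(weights)) {
    an <- analyzeNodes(model, trialSet)
    w <- stats::aggregate(abs(an$fits$b), by = list(neuron = an$fits$neuron),
                          FUN = mean)
    weights <- rep(NA_real_, nrow(model@J))
    weights[an$nkt@neuronMeta$node] <- w$x
  }
  active <- which(!is.na(weights))
  nTop <- max(1L, round(length(active) / 10))
  pool <- switch(group,
    high = active[order(weights[active], decreasing = TRUE)][seq_len(nTop)],
    low = active[order(weights[active])][seq_len(nTop)],
    random = active)
  if (length(pool) < nNodes)
    stop("group '", group, "' has fewer than nNodes nodes")
  base <- rnnPerformance(model, trialSet)
  rs <- .restoreSeed(seed)
  on.exit(rs())
  res <- lapply(seq_len(nBoot), function(bi) {
    sel <- sample(pool, nNodes)
    J <- model@J; B <- model@B; W <- model@W
    J[sel, ] <- 0; J[, sel] <- 0; B[sel, ] <- 0; W[, sel] <- 0
    fwd <- .rnnForward(J, B, W, model@tau, model@dt, trialSet$U,
                       keepStates = FALSE)
    perf <- .outputPerformance(fwd$Z, trialSet$Z)
    data.frame(group = group, boot = bi, mse = perf$mse, r2 = perf$r2,
               deficit = perf$mse - base$mse)
  })
  do.call(rbind, res)
}
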