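#' Build a double-reach task configuration
#'
#' Describes the condition geometry and event-timing distributions of the
#' memory-guided reach-sequence task. The `standard` variant has 18
#' conditions: three trial types (single reach, and double reach with the
#' second target displaced 120 deg clockwise or counterclockwise) crossed
#' with six first-reach directions on a regular hexagon. The `multi_angle`
#' variant extends the second-target displacement to 60 or 120 deg in both
#' directions plus 180 deg, giving 36 conditions (6 SR + 30 DR).
#'
#' Timing defaults: 400 ms cue, uniform 400-800 ms memory period (so the
#' cue-to-GO delay spans 800-1200 ms), reaction time 250 +/- 40 ms, reach
#' duration 250 +/- 30 ms, dwell on the first target 194 +/- 75 ms
#' (truncated at zero so event markers stay ordered).
#'
#' @param variant `"standard"` or `"multi_angle"`.
#' @param directions first-reach directions in degrees (default the hexagon
#'   `seq(0, 300, by = 60)`).
#' @param offsets signed second-target displacements in degrees
#'   (counterclockwise positive); defaults depend on `variant`.
#' @param trialsPerCondition trials per condition (default 20).
#' @param timing named list overriding any of `cueDuration`, `memoryRange`,
#'   `reactionMean`, `reactionSD`, `reachMean`, `reachSD`, `dwellMean`,
#'   `dwellSD` (ms).
#' @param seed integer seed used by [generateTrials()].
#' @return an object of class `"TaskConfig"` (a validated list) with a
#'   `conditions` data.frame (`type`, `theta1`, `theta2`, `theta21`).
#' @examples
#' nrow(makeTaskConfig("standard")$conditions)     # 18
#' nrow(makeTaskConfig("multi_angle")$conditions)  # 36
#' @export
makeTaskConfig <- function(variant = c("standard", "multi_angle"),
                           directions = seq(0, 300, by = 60),
                           offsets = NULL,
                           trialsPerCondition = 20,
                           timing = list(),
                           seed = 1L) {
  if (!is.character(variant) || !variant[1L] %in% c("standard", "multi_angle"))
    stop("unknown variant '", variant[1L],
         "'; valid variants are 'standard' and 'multi_angle'")
  variant <- variant[1L]
  if (is.null(offsets))
    offsets <- if (variant == "standard") c(120, -120)
               else c(60, -60, 120, -120, 180)
  directions <- wrapAngle(directions)

  tdef <- list(cueDuration = 400, memoryRange = c(400, 800),
               reactionMean = 250, reactionSD = 40,
               reachMean = 250, reachSD = 30,
               dwellMean = 194, dwellSD = 75)
  unknown <- setdiff(names(timing), names(tdef))
  if (length(unknown))
    stop("unknown timing field(s): ", paste(unknown, collapse = ", "))
  tdef[names(timing)] <- timing

  sr <- data.frame(type = "SR", theta1 = directions,
                   theta2 = NA_real_, theta21 = NA_real_)
  dr <- expand.grid(theta1 = directions, offset = offsets)
  dr <- data.frame(type = "DR", theta1 = dr$theta1,
                   theta2 = wrapAngle(dr$theta1 + dr$offset))
  dr$theta21 <- theta21FromTargets(dr$theta1, dr$theta2)
  conds <- rbind(sr, dr[, c("type", "theta1", "theta2", "theta21")])
  rownames(conds) <- NULL

  structure(list(variant = variant, directions = directions,
                 offsets = offsets, trialsPerCondition = trialsPerCondition,
                 timing = tdef, seed = as.integer(seed),
                 conditions = conds),
            class = "TaskConfig")
}

#' @export
print.TaskConfig <- function(x, ...) {
  cat("TaskConfig [", x$variant, "]:", nrow(x$conditions), "conditions (",
      sum(x$conditions$type == "SR"), "SR +",
      sum(x$conditions$type == "DR"), "DR ),",
      x$trialsPerCondition, "trials/condition\n")
  invisible(x)
}

#' Second-reach direction in execution coordinates
#'
#' Both reach targets sit on a circle around the start point; the second
#' reach is executed from the first target to the second, so its direction
#' in execution coordinates is the bearing of the chord between the two
#' target locations.
#'
#' @param theta1,theta2 first- and second-target directions from the center,
#'   in degrees (vectorised).
#' @return chord direction(s) in degrees, in `[0, 360)`.
#' @examples
#' theta21FromTargets(0, 120)  # 150
#' theta21FromTargets(0, 240)  # 210
#' @export
theta21FromTargets <- function(theta1, theta2) {
  if (any(!is.finite(theta1)) || any(!is.finite(theta2)))
    stop("target angles must be finite")
  if (any(wrapAngle(theta1) == wrapAngle(theta2)))
    stop("theta1 and theta2 coincide: chord direction undefined")
  atan2deg(sind(theta2) - sind(theta1), cosd(theta2) - cosd(theta1))
}

#' Generate a trial table from a task configuration
#'
#' Conditions are repeated `trialsPerCondition` times and pseudo-randomly
#' interleaved; event times are drawn per trial from the configured
#' distributions. Times are in ms with target onset `TO = 0`; `MO2`/`ME2`
#' are `NA` for single-reach trials.
#'
#' @param config a `"TaskConfig"` from [makeTaskConfig()].
#' @param seed optional seed overriding `config$seed`.
#' @return data.frame with columns `trial`, `condition`, `type`, `theta1`,
#'   `theta2`, `theta21`, `TO`, `GO`, `MO`, `ME`, `MO2`, `ME2`.
#' @export
generateTrials <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "TaskConfig"))
  if (config$trialsPerCondition < 1)
    stop("trialsPerCondition must be at least 1")
  tm <- config$timing
  conds <- config$conditions
  idx <- rep(seq_len(nrow(conds)), each = config$trialsPerCondition)
  n <- length(idx)

  rs <- .restoreSeed(seed)
  on.exit(rs())
  ord <- sample.int(n)               # pseudo-random interleaving
  idx <- idx[ord]
  tab <- conds[idx, , drop = FALSE]
  rownames(tab) <- NULL

  TO <- rep(0, n)
  GO <- TO + tm$cueDuration + stats::runif(n, tm$memoryRange[1], tm$memoryRange[2])
  MO <- GO + rnormTrunc(n, tm$reactionMean, tm$reactionSD, lower = 1)
  ME <- MO + rnormTrunc(n, tm$reachMean, tm$reachSD, lower = 1)
  isDR <- tab$type == "DR"
  MO2 <- ME2 <- rep(NA_real_, n)
  MO2[isDR] <- ME[isDR] + rnormTrunc(sum(isDR), tm$dwellMean, tm$dwellSD, lower = 0)
  ME2[isDR] <- MO2[isDR] + rnormTrunc(sum(isDR), tm$reachMean, tm$reachSD, lower = 1)

  data.frame(trial = seq_len(n), condition = idx, tab,
             TO = TO, GO = GO, MO = MO, ME = ME, MO2 = MO2, ME2 = ME2)
}

# Run expr-style RNG isolation: set seed, return a restorer for on.exit
.restoreSeed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Condition-preference gain of a surrogate neuron
#'
#' Direction-dependent gain of the surrogate rate model. The single-cosine
#' gain is `(1 + cos(theta1 - thetaPD)) / 2`; the additive (parallel-coding)
#' gain is `(1 + cos(theta1 - thetaPD) + cos(theta21 - thetaPD)) / 3`; the
#' multiplicative (gain-modulation) gain is
#' `(1 + cos(theta1 - thetaPD) + cos(theta1 - thetaPD) * cos(theta21 - thetaPD)) / 3`.
#' Values can be negative for the additive and multiplicative schemes (range
#' `[-1/3, 1]`); they are treated as abstract activations and are not
#' rectified here. The Poisson spike sampler applies an explicit floor at
#' zero instead (see [sampleSpikeTrains()]).
#'
#' @param scheme `"cosine"`, `"additive"` or `"multiplicative"`.
#' @param theta1 first-reach direction, deg.
#' @param theta21 second-reach direction in execution coordinates, deg
#'   (ignored by the cosine scheme).
#' @param thetaPD the neuron's intrinsic preferred direction, deg.
#' @return numeric gain(s).
#' @examples
#' conditionGain("cosine", 90, NA, 90)              # 1
#' conditionGain("multiplicative", 30, 30, 30)      # 1
#' @export
conditionGain <- function(scheme, theta1, theta21 = NA_real_, thetaPD) {
  c1 <- cosd(theta1 - thetaPD)
  switch(scheme,
    cosine = (1 + c1) / 2,
    additive = (1 + c1 + cosd(theta21 - thetaPD)) / 3,
    multiplicative = (1 + c1 + c1 * cosd(theta21 - thetaPD)) / 3,
    stop("unknown scheme '", scheme,
         "'; valid schemes: cosine, additive, multiplicative")
  )
}

#' Surrogate single-trial rate profile
#'
#' Time course of a surrogate neuron: constant preparatory activity
#' `phi * b` before the response latency `tau`, then a Gaussian response
#' bump `b * exp(-(t - tau - mu0)^2 / (2 sigma^2))` with
#' `mu0 = sigma * sqrt(-2 * log(phi))`, which makes the profile continuous
#' at `t = tau`. Optional additive Gaussian noise (SD `noiseSD`) is drawn
#' independently per time sample.
#'
#' @param times sample times in ms (monotone increasing).
#' @param gain condition gain `b` (see [conditionGain()]).
#' @param tau response latency in ms.
#' @param sigma response duration parameter in ms (> 0).
#' @param phi preparatory amplitude constant in (0, 1]; default 0.2.
#' @param noiseSD SD of additive noise (default 0.01; 0 disables noise).
#' @return numeric rate series, same length as `times`.
#' @export
simulateRateProfile <- function(times, gain, tau, sigma, phi = 0.2,
                                noiseSD = 0.01) {
  if (is.unsorted(times)) stop("times must be monotone increasing")
  if (phi <= 0 || phi > 1) stop("phi must lie in (0, 1]: mu0 undefined")
  if (sigma <= 0) stop("sigma must be positive")
  mu0 <- sigma * sqrt(-2 * log(phi))
  f <- ifelse(times < tau,
              phi * gain,
              gain * exp(-(times - tau - mu0)^2 / (2 * sigma^2)))
  if (noiseSD > 0) f <- f + stats::rnorm(length(times), 0, noiseSD)
  f
}

#' Generate a surrogate population dataset
#'
#' Builds an [NKTDataset-class] of trial-resolved rate traces aligned to
#' movement onset. For the `cosine`, `additive` and `multiplicative` schemes
#' each neuron follows the surrogate rate profile of
#' [simulateRateProfile()], with the condition gain given by its scheme
#' (single-reach trials always use the cosine gain, since they have no
#' second reach). For `scheme = "full"` the rates follow the full joint
#' tuning model `a1*cos(th1-PD) + a2*cos(th21-PD) + b*cos(th1-PD)*cos(th21-PD) + c`
#' with per-neuron ground-truth coefficients (plus Gaussian noise), constant
#' across bins unless a coefficient schedule is supplied; the truth is
#' stored in `neuronMeta` for recovery tests.
#'
#' @param nNeurons number of neurons.
#' @param scheme `"cosine"`, `"additive"`, `"multiplicative"` or `"full"`.
#' @param config a `"TaskConfig"`.
#' @param seed integer seed.
#' @param pds optional preferred directions (deg); default uniform random,
#'   or evenly spaced when `evenPDs = TRUE`.
#' @param evenPDs use evenly spaced PDs `(0:(n-1)) * 360/n` (useful for
#'   analytic population-vector checks).
#' @param truth for `scheme = "full"`: data.frame with columns `a1`, `a2`,
#'   `b`, `c` (and optionally `thetaPD`), one row per neuron; default draws
#'   coefficients uniformly from [0.2, 0.8] with `c` in [0.2, 0.5].
#' @param schedule optional function `f(binCenter)` returning a length-3
#'   multiplier for `(a1, a2, b)` at that bin (full scheme only), used to
#'   script coefficient transitions over time.
#' @param window time window in ms relative to `alignment` (default
#'   `c(-300, 300)`).
#' @param dt bin spacing in ms (default 50, matching the population-vector
#'   readout grid).
#' @param tauMean,tauSD response-latency distribution across neurons (ms).
#' @param sigma response duration parameter (ms).
#' @param phi preparatory amplitude constant.
#' @param noiseSD additive noise SD (per time sample).
#' @param alignment event marker at time zero (default `"MO"`).
#' @return an [NKTDataset-class]; `neuronMeta` holds `thetaPD`, `tau`, and
#'   ground-truth coefficients for the full scheme.
#' @export
generatePopulationDataset <- function(nNeurons, scheme, config, seed = 1L,
                                      pds = NULL, evenPDs = FALSE,
                                      truth = NULL, schedule = NULL,
                                      window = c(-300, 300), dt = 50,
                                      tauMean = 150, tauSD = 30,
                                      sigma = 150, phi = 0.2, noiseSD = 0.01,
                                      alignment = "MO") {
  stopifnot(nNeurons >= 1, inherits(config, "TaskConfig"))
  scheme <- match.arg(scheme, c("cosine", "additive", "multiplicative", "full"))
  rs <- .restoreSeed(seed)
  on.exit(rs())

  trials <- generateTrials(config, seed = seed)
  K <- nrow(trials)
  times <- seq(window[1], window[2], by = dt)
  Tn <- length(times)

  if (is.null(pds)) {
    pds <- if (evenPDs) (seq_len(nNeurons) - 1) * 360 / nNeurons
           else stats::runif(nNeurons, 0, 360)
  }
  pds <- wrapAngle(pds)
  if (length(pds) != nNeurons)
    stop("length of pds must match nNeurons")
  taus <- stats::rnorm(nNeurons, tauMean, tauSD)

  arr <- array(0, dim = c(nNeurons, K, Tn))
  isDR <- trials$type == "DR"

  if (scheme == "full") {
    if (is.null(truth)) {
      truth <- data.frame(a1 = stats::runif(nNeurons, 0.2, 0.8),
                          a2 = stats::runif(nNeurons, 0.2, 0.8),
                          b  = stats::runif(nNeurons, 0.2, 0.8),
                          c  = stats::runif(nNeurons, 0.2, 0.5))
    }
    if (nrow(truth) != nNeurons)
      stop("truth must have one row per neuron")
    if (!is.null(truth$thetaPD)) pds <- wrapAngle(truth$thetaPD)
    c1 <- outer(pds, trials$theta1, function(p, t) cosd(t - p))   # N x K
    c2 <- outer(pds, trials$theta21, function(p, t) cosd(t - p))
    c2[, !isDR] <- 0                                              # SR: no 2nd reach terms
    for (ti in seq_len(Tn)) {
      m <- if (is.null(schedule)) c(1, 1, 1) else schedule(times[ti])
      mu <- truth$a1 * m[1] * c1 + truth$a2 * m[2] * c2 +
            truth$b * m[3] * c1 * c2 + truth$c
      arr[, , ti] <- mu
    }
    if (noiseSD > 0)
      arr <- arr + array(stats::rnorm(length(arr), 0, noiseSD), dim = dim(arr))
    meta <- data.frame(thetaPD = pds, tau = taus,
                       truth[setdiff(names(truth), "thetaPD")])
  } else {
    gains <- matrix(0, nNeurons, K)
    for (n in seq_len(nNeurons)) {
      g <- conditionGain("cosine", trials$theta1, NA, pds[n])
      if (scheme != "cosine" && any(isDR))
        g[isDR] <- conditionGain(scheme, trials$theta1[isDR],
                                 trials$theta21[isDR], pds[n])
      gains[n, ] <- g
    }
    mu0 <- sigma * sqrt(-2 * log(phi))
    for (ti in seq_len(Tn)) {
      tshape <- ifelse(times[ti] < taus, phi,
                       exp(-(times[ti] - taus - mu0)^2 / (2 * sigma^2)))  # per neuron
      arr[, , ti] <- gains * tshape
    }
    if (noiseSD > 0)
      arr <- arr + array(stats::rnorm(length(arr), 0, noiseSD), dim = dim(arr))
    meta <- data.frame(thetaPD = pds, tau = taus)
  }

  new("NKTDataset", rates = arr, binCenters = times, alignment = alignment,
      trials = trials, neuronMeta = meta)
}

#' Sample spike trains from a rate profile
#'
#' Inhomogeneous Poisson sampling by thinning of a piecewise-constant rate
#' function. Surrogate "rates" can be negative (they are abstract
#' activations); sampling requires an explicit floor at zero, applied when
#' `floorAtZero = TRUE` (the default) and an error otherwise.
#'
#' @param times sample times in ms.
#' @param rateSeries rates in spikes/s at `times`.
#' @param seed optional integer seed.
#' @param floorAtZero clamp negative rates to zero before sampling.
#' @return sorted numeric vector of spike times (ms) within
#'   `range(times)`.
#' @export
sampleSpikeTrains <- function(times, rateSeries, seed = NULL,
                              floorAtZero = TRUE) {
  stopifnot(length(times) == length(rateSeries))
  if (any(rateSeries < 0)) {
    if (!floorAtZero)
      stop("negative rates: set floorAtZero = TRUE to clamp them")
    rateSeries <- pmax(rateSeries, 0)
  }
  if (!is.null(seed)) {
    rs <- .restoreSeed(seed)
    on.exit(rs())
  }
  rmax <- max(rateSeries)
  if (rmax <= 0) return(numeric(0))
  span <- range(times)
  durS <- (span[2] - span[1]) / 1000
  nCand <- stats::rpois(1, rmax * durS)
  if (nCand == 0) return(numeric(0))
  cand <- sort(stats::runif(nCand, span[1], span[2]))
  rAt <- stats::approx(times, rateSeries, xout = cand, method = "constant",
                       rule = 2)$y
  cand[stats::runif(nCand) < rAt / rmax]
}
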