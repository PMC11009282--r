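# Joint cosine-tuning models.
#
# All models share one intrinsic preferred direction thetaPD per fit. Given
# thetaPD they are linear in the remaining coefficients, so fitting profiles
# thetaPD on a degree grid with an ordinary least-squares solve at each grid
# point, then refines the best grid point by golden-section search. This is
# convex in the coefficients at fixed thetaPD, immune to local minima of
# generic nonlinear least squares, and exactly reproducible.

.tuningModels <- c("cosine_theta1", "cosine_theta2", "cosine_theta21",
                   "additive", "multiplicative", "full")

# parameter count p includes thetaPD itself
.tuningP <- c(cosine_theta1 = 3L, cosine_theta2 = 3L, cosine_theta21 = 3L,
              additive = 4L, multiplicative = 4L, full = 5L)

# design matrix at fixed PD; columns ordered (a1[, a2][, b], c)
.tuningDesign <- function(model, theta1, theta21, pd) {
  c1 <- cosd(theta1 - pd)
  switch(model,
    cosine_theta1  = cbind(a1 = c1, c = 1),
    cosine_theta2  = ,   # caller passes the relevant angle as theta1
    cosine_theta21 = cbind(a1 = cosd(theta21 - pd), c = 1),
    additive       = cbind(a1 = c1, a2 = cosd(theta21 - pd), c = 1),
    multiplicative = cbind(a1 = c1, b = c1 * cosd(theta21 - pd), c = 1),
    full = {
      c2 <- cosd(theta21 - pd)
      cbind(a1 = c1, a2 = c2, b = c1 * c2, c = 1)
    },
    stop("unknown model '", model, "'")
  )
}

# Multi-series PD-profile fit.
# Y: observations x series matrix (shared angles across series).
# Returns per-series thetaPD, coefficient matrix, sse, sst, plus an
# aliasing flag from the worst design-matrix condition number seen.
.pdProfileFitMulti <- function(Y, theta1, theta21, model, gridStep = 1,
                               refine = TRUE) {
  Y <- as.matrix(Y)
  n <- nrow(Y); M <- ncol(Y)
  grid <- seq(0, 360 - gridStep, by = gridStep)
  yss <- colSums(Y^2)
  bestSSE <- rep(Inf, M)
  bestPD <- numeric(M)
  p1 <- ncol(.tuningDesign(model, theta1[1], theta21[1], 0))
  bestCoef <- matrix(NA_real_, p1, M)
  kappaMax <- 0

  for (pd in grid) {
    X <- .tuningDesign(model, theta1, theta21, pd)
    qrX <- qr(X)
    kappaMax <- max(kappaMax, kappa(qrX$qr, exact = FALSE))
    cf <- qr.coef(qrX, Y)               # p x M (NA rows if rank-deficient)
    qty <- qr.qty(qrX, Y)[seq_len(qrX$rank), , drop = FALSE]
    sse <- pmax(yss - colSums(qty^2), 0)
    upd <- sse < bestSSE
    if (any(upd)) {
      bestSSE[upd] <- sse[upd]
      bestPD[upd] <- pd
      bestCoef[, upd] <- cf[, upd, drop = FALSE]
    }
  }

  if (refine) {
    sseAt <- function(pd, y) {
      X <- .tuningDesign(model, theta1, theta21, pd)
      f <- stats::lm.fit(X, y)
      sum(f$residuals^2)
    }
    for (j in seq_len(M)) {
      opt <- .goldenSection(function(pd) sseAt(pd, Y[, j]),
                            bestPD[j] - gridStep, bestPD[j] + gridStep,
                            tol = 1e-4)
      X <- .tuningDesign(model, theta1, theta21, opt$minimum)
      f <- stats::lm.fit(X, Y[, j])
      sse <- sum(f$residuals^2)
      if (sse <= bestSSE[j]) {   # keep the grid point on a refinement tie
        bestSSE[j] <- sse
        bestPD[j] <- opt$minimum
        bestCoef[, j] <- f$coefficients
      }
    }
  }

  # canonicalise the sign/PD ambiguity: PD -> PD + 180 with
  # (a1, a2) -> (-a1, -a2) leaves predictions unchanged (b, c invariant)
  cn <- colnames(.tuningDesign(model, theta1[1], theta21[1], 0))
  rownames(bestCoef) <- cn
  flip <- function(j) {
    bestPD[j] <<- wrapAngle(bestPD[j] + 180)
    for (nm in intersect(c("a1", "a2"), cn))
      bestCoef[nm, j] <<- -bestCoef[nm, j]
  }
  for (j in seq_len(M)) {
    a1 <- bestCoef["a1", j]
    a2 <- if ("a2" %in% cn) bestCoef["a2", j] else NA_real_
    if (!is.na(a1) && a1 < 0) flip(j)
    else if (!is.na(a1) && a1 == 0 && !is.na(a2) && a2 < 0) flip(j)
    a1 <- bestCoef["a1", j]; a2 <- if ("a2" %in% cn) bestCoef["a2", j] else NA_real_
    if (!is.na(a1) && a1 == 0 && (is.na(a2) || a2 == 0))
      bestPD[j] <- bestPD[j] %% 180
  }
  bestPD <- wrapAngle(bestPD)

  sst <- colSums(sweep(Y, 2, colMeans(Y))^2)
  list(thetaPD = bestPD, coef = bestCoef, sse = bestSSE, sst = sst,
       n = n, p = unname(.tuningP[model]), aliased = kappaMax > 1e6)
}

.goldenSection <- function(f, lo, hi, tol = 1e-4) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 < f2) { b <- c2; c2 <- c1; f2 <- f1
                   c1 <- b - gr * (b - a); f1 <- f(c1) }
    else         { a <- c1; c1 <- c2; f1 <- f2
                   c2 <- a + gr * (b - a); f2 <- f(c2) }
  }
  x <- (a + b) / 2
  list(minimum = x, value = f(x))
}

.makeTuningFit <- function(model, fit, j = 1L, binCenter = NA_real_,
                           extraFlags = character(0)) {
  cf <- fit$coef[, j]
  getc <- function(nm) if (nm %in% names(cf)) unname(cf[nm]) else NA_real_
  sse <- fit$sse[j]; sst <- fit$sst[j]
  flags <- extraFlags
  if (fit$aliased) flags <- c(flags, "aliased")
  if (sst <= .Machine$double.eps * fit$n) {
    r2 <- 0; r2a <- 0
    flags <- c(flags, "constant")
  } else {
    r2 <- 1 - sse / sst
    r2a <- adjustedR2(sse, sst, fit$n, fit$p)
  }
  new("TuningFit", model = model,
      a1 = getc("a1"), a2 = getc("a2"), b = getc("b"), c = getc("c"),
      thetaPD = fit$thetaPD[j], r2 = r2, r2adj = r2a,
      n = as.integer(fit$n), p = as.integer(fit$p),
      sse = sse, sst = sst, binCenter = binCenter, flags = flags)
}

#' Fit the single-cosine direction model
#'
#' Least-squares fit of `FR = a * cos(theta - thetaPD) + c` with the
#' preferred direction profiled on a degree grid and refined by
#' golden-section search. The amplitude is reported as `a1 >= 0` (the sign
#' ambiguity is resolved by flipping the PD by 180 deg).
#'
#' @param rates numeric response vector (e.g. condition-averaged rates).
#' @param directions movement directions in degrees, same length.
#' @param gridStep PD grid resolution in degrees (default 1).
#' @param refine refine the best grid point by golden-section search.
#' @return a [TuningFit-class] with `p = 3` parameters.
#' @examples
#' th <- seq(0, 300, by = 60)
#' fit <- fitDirectionModel(2 + cos((th - 30) * pi / 180), th)
#' fit@thetaPD  # ~30
#' @export
fitDirectionModel <- function(rates, directions, gridStep = 1, refine = TRUE) {
  if (length(unique(wrapAngle(directions))) < 4)
    stop("need at least 4 distinct directions")
  if (length(rates) < .tuningP["cosine_theta1"])
    stop("fewer observations than parameters")
  fit <- .pdProfileFitMulti(matrix(rates, ncol = 1), directions, directions,
                            "cosine_theta1", gridStep, refine)
  flags <- character(0)
  if (stats::sd(rates) == 0) {
    fit$coef["a1", 1] <- 0
    flags <- "constant"
  }
  .makeTuningFit("cosine_theta1", fit, extraFlags = flags)
}

#' Fit a joint sequence-tuning model
#'
#' Fits one of the joint directional tuning models to double-reach
#' responses, with a single shared preferred direction per fit:
#' \describe{
#'   \item{additive}{`a1*cos(th1 - PD) + a2*cos(th21 - PD) + c` (parallel
#'     coding: independent tuning to the two reaches).}
#'   \item{multiplicative}{`a1*cos(th1 - PD) + b*cos(th21 - PD)*cos(th1 - PD) + c`
#'     (gain modulation of the first-reach tuning by the second reach).}
#'   \item{full}{both additive and multiplicative terms.}
#' }
#' The PD is profiled on a degree grid (the model is linear in the
#' coefficients at fixed PD) and refined by golden-section search; the
#' `a1 >= 0` sign convention is applied. Near-collinear designs (e.g. the
#' standard task's single displacement magnitude) are flagged `"aliased"`.
#'
#' @param rates response vector over double-reach conditions.
#' @param theta1s first-reach directions (deg).
#' @param theta21s second-reach directions in execution coordinates (deg).
#' @param model `"additive"`, `"multiplicative"` or `"full"` (or one of the
#'   single-cosine variants `"cosine_theta1"`, `"cosine_theta21"`).
#' @param gridStep,refine see [fitDirectionModel()].
#' @return a [TuningFit-class].
#' @export
fitJointModel <- function(rates, theta1s, theta21s,
                          model = c("additive", "multiplicative", "full",
                                    "cosine_theta1", "cosine_theta21"),
                          gridStep = 1, refine = TRUE) {
  model <- match.arg(model)
  n <- length(rates)
  stopifnot(length(theta1s) == n, length(theta21s) == n)
  if (n <= .tuningP[model] - 1)
    stop("fewer observations than coefficients")
  flags <- character(0)
  if (stats::sd(rates) == 0) flags <- "constant"
  fit <- .pdProfileFitMulti(matrix(rates, ncol = 1), theta1s, theta21s,
                            model, gridStep, refine)
  if ("constant" %in% flags) fit$coef[, 1][] <- c(rep(0, nrow(fit$coef) - 1),
                                                  rates[1])
  .makeTuningFit(model, fit, extraFlags = flags)
}

#' Adjusted R-squared
#'
#' `1 - ((n - 1) / (n - p)) * SSE / SST`, penalising the goodness-of-fit
#' for the number of fitted parameters so that models with different
#' coefficient counts are comparable.
#'
#' @param sse residual sum of squares.
#' @param sst total sum of squares (> 0).
#' @param n number of observations (> p).
#' @param p number of fitted parameters.
#' @return adjusted R-squared.
#' @examples
#' adjustedR2(sse = 0.5, sst = 1, n = 30, p = 5)  # 0.42
#' @export
adjustedR2 <- function(sse, sst, n, p) {
  if (any(n <= p)) stop("n must exceed p")
  if (any(sst <= 0)) stop("sst must be positive")
  1 - ((n - 1) / (n - p)) * (sse / sst)
}

#' Product-to-sum expansion of the multiplicative term
#'
#' The multiplicative (gain) term `b*cos(th1 - PD)*cos(th21 - PD)` equals,
#' by the exact product-to-sum identity,
#' `b/2 * cos(th21 - th1) + b/2 * cos(th1 + th21 - 2*PD)`: a constant in
#' direction plus a second-harmonic ("frequency-doubled") component of
#' amplitude `b/2`. Returns both sides for equality testing.
#'
#' @param theta1,theta21 reach directions (deg, vectorised).
#' @param thetaPD preferred direction (deg).
#' @param b multiplicative coefficient.
#' @return list with `lhs` (the product form) and `rhs` (the summation
#'   form).
#' @export
productToSumCheck <- function(theta1, theta21, thetaPD, b) {
  lhs <- b * cosd(theta1 - thetaPD) * cosd(theta21 - thetaPD)
  rhs <- b / 2 * cosd(theta21 - theta1) +
         b / 2 * cosd(theta1 + theta21 - 2 * thetaPD)
  list(lhs = lhs, rhs = rhs)
}

#' Sliding-window tuning regression over a population
#'
#' Condition-averages the double-reach trials of an [NKTDataset-class] and
#' fits the requested tuning models per neuron and time bin. Expects rates
#' already normalised for regression (see [normalizeForRegression()]);
#' when `bin`/`step` are given the dataset is first re-binned with
#' [assembleNKT()], otherwise the dataset's own bins are used.
#'
#' @param nkt an [NKTDataset-class].
#' @param models character vector of models (see [fitJointModel()]).
#' @param bin,step optional sliding-window width and step in ms.
#' @param gridStep PD grid resolution (deg).
#' @param refine golden-section refinement of the PD.
#' @param trialTypes which trial types enter the condition average
#'   (default `"DR"`).
#' @return data.frame with one row per neuron x bin x model: coefficients,
#'   `thetaPD`, `r2`, `r2adj`, `sse`, `sst`, `flags`.
#' @export
slidingWindowRegression <- function(nkt, models, bin = NULL, step = NULL,
                                    gridStep = 1, refine = TRUE,
                                    trialTypes = "DR") {
  stopifnot(is(nkt, "NKTDataset"))
  if (length(models) == 0) stop("empty model list")
  models <- match.arg(models, .tuningModels, several.ok = TRUE)
  if (!is.null(bin) && !is.null(step)) {
    span <- range(binCenters(nkt))
    nkt <- assembleNKT(nkt, binWidth = bin, step = step, window = span)
  }
  keep <- trialTable(nkt)$type %in% trialTypes
  tr <- trialTable(nkt)[keep, , drop = FALSE]
  arr <- rates(nkt)[, keep, , drop = FALSE]
  condIds <- interaction(tr$theta1, tr$theta21, drop = TRUE)
  conds <- !duplicated(condIds)
  th1 <- tr$theta1[conds]; th21 <- tr$theta21[conds]
  condLevels <- condIds[conds]
  nc <- length(condLevels)
  N <- dim(arr)[1]; Tn <- dim(arr)[3]
  bc <- binCenters(nkt)

  # condition-average: nc x N per bin
  out <- vector("list", length(models) * Tn)
  k <- 0L
  for (ti in seq_len(Tn)) {
    Y <- matrix(0, nc, N)
    for (ci in seq_len(nc)) {
      m <- condIds == condLevels[ci]
      Y[ci, ] <- rowMeans(arr[, m, ti, drop = FALSE])
    }
    for (mod in models) {
      fit <- .pdProfileFitMulti(Y, th1, th21, mod, gridStep, refine)
      rows <- lapply(seq_len(N), function(j)
        as.data.frame(.makeTuningFit(mod, fit, j, binCenter = bc[ti])))
      df <- do.call(rbind, rows)
      df$neuron <- seq_len(N)
      k <- k + 1L
      out[[k]] <- df
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  res[order(res$model, res$neuron, res$binCenter),
      c("neuron", "binCenter", "model", "a1", "a2", "b", "c", "thetaPD",
        "r2", "r2adj", "n", "p", "sse", "sst", "flags")]
}

# Signed-rank Z statistic (normal approximation, tie-corrected, zero
# differences dropped); returned with the number of non-zero pairs.
.signedRankZ <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) return(list(Z = 0, m = 0, W = NA_real_))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- m * (m + 1) / 4
  ties <- table(r)
  sig2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
  list(Z = (W - mu) / sqrt(sig2), m = m, W = W)
}

#' Population comparison of two model fits
#'
#' Compares paired per-neuron goodness-of-fit (adjusted R-squared) between
#' two models at each time bin with a two-tailed Wilcoxon signed-rank test,
#' reports the effect size `r = |Z| / sqrt(n)` (n = number of pairs, Z from
#' the tie-corrected normal approximation), and marks the winning model
#' where `p < alpha`.
#'
#' @param fitsA,fitsB data.frames from [slidingWindowRegression()] (one
#'   model each), or numeric matrices neurons x bins of adjusted R-squared.
#' @param alpha per-bin significance threshold (default 0.0005, reported
#'   per bin without multiplicity correction).
#' @return data.frame per bin: `binCenter`, `p`, `effectR`,
#'   `winner` ("A", "B" or "none"), `meanA`, `meanB`, `n`.
#' @export
compareModelsPopulation <- function(fitsA, fitsB, alpha = 5e-4) {
  toMat <- function(f) {
    if (is.matrix(f)) return(f)
    stopifnot(is.data.frame(f))
    if (length(unique(f$model)) != 1)
      stop("each input must contain fits of a single model")
    stats::xtabs(r2adj ~ neuron + binCenter, data = f)
  }
  A <- toMat(fitsA); B <- toMat(fitsB)
  if (!all(dim(A) == dim(B)))
    stop("inputs must be paired: same neurons and bins")
  bins <- if (is.null(colnames(A))) seq_len(ncol(A)) else
    as.numeric(colnames(A))
  res <- lapply(seq_len(ncol(A)), function(ti) {
    a <- A[, ti]; b <- B[, ti]
    if (all(a == b)) {
      p <- 1; r <- 0
    } else {
      p <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value
      sr <- .signedRankZ(a, b)
      r <- min(abs(sr$Z) / sqrt(length(a)), 1)
    }
    data.frame(binCenter = bins[ti], p = p, effectR = r,
               winner = if (p >= alpha) "none" else
                 if (mean(a) > mean(b)) "A" else "B",
               meanA = mean(a), meanB = mean(b), n = length(a))
  })
  do.call(rbind, res)
}

#' Permutation chance level for tuning coefficients
#'
#' Chance-level bands for the full-model coefficient magnitudes. At each
#' bin, condition labels are shuffled across the condition-averaged
#' responses (breaking the direction-response relation while preserving the
#' response distribution), the full model is refitted, and the
#' population-mean absolute coefficients |a1|, |a2|, |b| are collected over
#' permutations.
#'
#' @param nkt an [NKTDataset-class] of (normalised) rates.
#' @param nPerm number of permutations (default 1000; < 100 warns).
#' @param seed integer seed.
#' @param probs quantiles of the permutation distribution to report
#'   (default `c(0.025, 0.975)`).
#' @param gridStep PD grid step used for the permuted refits (deg).
#' @return data.frame per bin and coefficient: permutation `mean`, `lo`,
#'   `hi` quantiles of the population-mean |coefficient|, plus the observed
#'   (unpermuted) value in `observed`.
#' @export
permutationCoefficientChance <- function(nkt, nPerm = 1000, seed = 1L,
                                         probs = c(0.025, 0.975),
                                         gridStep = 1) {
  stopifnot(is(nkt, "NKTDataset"))
  if (nPerm < 100) warning("nPerm < 100 gives coarse chance bands")
  rs <- .restoreSeed(seed)
  on.exit(rs())

  keep <- trialTable(nkt)$type == "DR"
  if (!any(keep)) stop("permutation chance level needs DR trials")
  tr <- trialTable(nkt)[keep, , drop = FALSE]
  arr <- rates(nkt)[, keep, , drop = FALSE]
  condIds <- interaction(tr$theta1, tr$theta21, drop = TRUE)
  lv <- levels(condIds)
  nc <- length(lv)
  first <- match(lv, condIds)
  th1 <- tr$theta1[first]; th21 <- tr$theta21[first]
  N <- dim(arr)[1]; Tn <- dim(arr)[3]
  bc <- binCenters(nkt)

  perms <- replicate(nPerm, sample.int(nc), simplify = FALSE)
  out <- vector("list", Tn)
  for (ti in seq_len(Tn)) {
    Y <- sapply(lv, function(l) rowMeans(arr[, condIds == l, ti, drop = FALSE]))
    Y <- t(Y)                               # nc x N
    # observed fit
    obs <- .pdProfileFitMulti(Y, th1, th21, "full", gridStep, refine = FALSE)
    # all permutations at once: columns are neuron x perm
    YP <- do.call(cbind, lapply(perms, function(pm) Y[pm, , drop = FALSE]))
    pf <- .pdProfileFitMulti(YP, th1, th21, "full", gridStep, refine = FALSE)
    res <- lapply(c("a1", "a2", "b"), function(nm) {
      permMeans <- colMeans(matrix(abs(pf$coef[nm, ]), nrow = N))
      q <- stats::quantile(permMeans, probs, names = FALSE)
      data.frame(binCenter = bc[ti], coefficient = nm,
                 observed = mean(abs(obs$coef[nm, ])),
                 mean = mean(permMeans), lo = q[1], hi = q[2],
                 nPerm = nPerm)
    })
    out[[ti]] <- do.call(rbind, res)
  }
  do.call(rbind, out)
}

#' Fourier decomposition of a direction tuning curve
#'
#' Harmonic amplitudes and phases (orders 0-2) of responses sampled at
#' equally spaced directions. A pure cosine tuning curve carries all its
#' power in the first harmonic; a multiplicative (gain-modulated) tuning
#' curve swept in `theta1` at fixed `theta21 - theta1` acquires a second
#' harmonic of amplitude `b/2` (frequency doubling).
#'
#' @param rates responses at `directions`.
#' @param directions equally spaced directions in degrees (at least 6 for
#'   harmonic 2 to be resolvable).
#' @return data.frame with `harmonic` (0, 1, 2), `amplitude`, `phase`
#'   (deg).
#' @export
fourierTuningCurve <- function(rates, directions) {
  M <- length(directions)
  if (M < 6) stop("need at least 6 equally spaced directions")
  o <- order(wrapAngle(directions))
  th <- wrapAngle(directions)[o]
  y <- rates[o]
  gaps <- diff(c(th, th[1] + 360))
  if (max(abs(gaps - 360 / M)) > 1e-8)
    stop("directions must be equally spaced on the circle")
  res <- lapply(0:2, function(h) {
    z <- sum(y * exp(-1i * h * deg2rad(th)))
    amp <- if (h == 0) Mod(z) / M else 2 * Mod(z) / M
    data.frame(harmonic = h, amplitude = amp,
               phase = wrapAngle(rad2deg(Arg(z))))
  })
  do.call(rbind, res)
}
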