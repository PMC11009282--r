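# PCA-LDA-QR state-space analysis of preparatory activity.
#
# Fisher LDA is solved by symmetric eigendecomposition of the
# within/between scatter problem with a small ridge (1e-6 relative to the
# mean within-class variance) for numerical stability; eigenvector signs
# are fixed deterministically so repeated fits are identical.

# Fisher discriminant axes: columns are the (C-1) axes in feature space.
.fisherLDA <- function(X, labels, ridge = 1e-6) {
  labels <- droplevels(as.factor(labels))
  classes <- levels(labels)
  C <- length(classes)
  d <- ncol(X)
  gm <- colMeans(X)
  Sw <- matrix(0, d, d)
  Sb <- matrix(0, d, d)
  for (cl in classes) {
    Xi <- X[labels == cl, , drop = FALSE]
    mi <- colMeans(Xi)
    Xc <- sweep(Xi, 2, mi)
    Sw <- Sw + crossprod(Xc)
    Sb <- Sb + nrow(Xi) * tcrossprod(mi - gm)
  }
  Sw <- Sw / nrow(X) + ridge * mean(diag(Sw) / nrow(X) + 1) * diag(d)
  Sb <- Sb / nrow(X)
  # symmetric generalised eigenproblem via Sw^{-1/2}
  es <- eigen(Sw, symmetric = TRUE)
  Wh <- es$vectors %*% diag(1 / sqrt(pmax(es$values, 1e-12)), d) %*%
    t(es$vectors)
  M <- Wh %*% Sb %*% Wh
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
  k <- min(C - 1, d)
  A <- Wh %*% ev$vectors[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-magnitude entry positive
  for (j in seq_len(k)) {
    i <- which.max(abs(A[, j]))
    if (A[i, j] < 0) A[, j] <- -A[, j]
  }
  A
}

# Nearest class centroid classification in a discriminant space
.centroidClassify <- function(train, trainLabels, test) {
  trainLabels <- droplevels(as.factor(trainLabels))
  cent <- sapply(levels(trainLabels), function(cl)
    colMeans(train[trainLabels == cl, , drop = FALSE]))
  cent <- matrix(cent, ncol = nlevels(trainLabels))
  d2 <- sapply(seq_len(ncol(cent)), function(j)
    rowSums(sweep(test, 2, cent[, j])^2))
  levels(trainLabels)[max.col(-matrix(d2, nrow = nrow(test)),
                              ties.method = "first")]
}

# Stratified fold assignment, reproducible given the current RNG state
.stratifiedFolds <- function(labels, folds) {
  labels <- as.factor(labels)
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

# CV accuracy of PCA(P) + LDA + nearest centroid
.cvAccuracy <- function(X, labels, P, folds) {
  labels <- droplevels(as.factor(labels))
  fold <- .stratifiedFolds(labels, folds)
  correct <- 0L
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- !tr
    mu <- colMeans(X[tr, , drop = FALSE])
    Xc <- sweep(X[tr, , drop = FALSE], 2, mu)
    sv <- svd(Xc, nu = 0, nv = min(P, ncol(X), sum(tr) - 1))
    V <- sv$v
    Str <- Xc %*% V
    Ste <- sweep(X[te, , drop = FALSE], 2, mu) %*% V
    A <- .fisherLDA(Str, labels[tr])
    pred <- .centroidClassify(Str %*% A, labels[tr],
                              matrix(Ste %*% A, ncol = ncol(A)))
    correct <- correct + sum(pred == as.character(labels[te]))
  }
  correct / length(labels)
}

#' Choose the number of principal components by cross-validation
#'
#' Scans candidate PCA dimensionalities and returns the one maximising the
#' stratified k-fold cross-validated accuracy of an LDA classifier built on
#' the PCA scores; ties resolve to the smallest dimensionality.
#'
#' @param X trials x features matrix (z-scored).
#' @param labels condition labels, one per trial.
#' @param folds number of CV folds (default 10; must be > 1).
#' @param candidates candidate numbers of PCs (default
#'   `C:min(30, n-2, d)` where C is the class count).
#' @param seed seed for the fold assignment.
#' @return list with `P` (chosen number), `accuracy` (named vector of CV
#'   accuracies per candidate).
#' @export
chooseNumPCs <- function(X, labels, folds = 10, candidates = NULL,
                         seed = 1L) {
  if (folds < 2) stop("folds must be at least 2")
  labels <- droplevels(as.factor(labels))
  if (min(table(labels)) < folds)
    stop("every class needs at least `folds` trials for stratified CV")
  X <- as.matrix(X)
  C <- nlevels(labels)
  if (is.null(candidates))
    candidates <- seq(C, min(30L, nrow(X) - 2L, ncol(X)))
  rs <- .restoreSeed(seed)
  on.exit(rs())
  acc <- vapply(candidates, function(P) .cvAccuracy(X, labels, P, folds),
                numeric(1))
  names(acc) <- candidates
  list(P = candidates[which.max(acc)], accuracy = acc)
}

# Reshape the preparatory window of a z-scored NKT into K x (N*T) features
.trialFeatures <- function(nkt, window, binWidth) {
  bc <- binCenters(nkt)
  edges <- seq(window[1], window[2], by = binWidth)
  Tn <- length(edges) - 1
  arr <- rates(nkt)
  N <- dim(arr)[1]; K <- dim(arr)[2]
  feat <- matrix(0, K, N * Tn)
  for (t in seq_len(Tn)) {
    sel <- bc >= edges[t] & bc < edges[t + 1]
    if (!any(sel)) stop("no bins inside feature window [",
                        edges[t], ", ", edges[t + 1], ") ms")
    feat[, (t - 1) * N + seq_len(N)] <-
      t(apply(arr[, , sel, drop = FALSE], c(1, 2), mean))
  }
  feat
}

#' Fit a PCA-LDA-QR state embedding
#'
#' Embeds preparatory trial states: each trial is described by its
#' z-scored rates in `T = (window span)/binWidth` coarse bins (default two
#' 300-ms bins spanning the 600 ms before GO), features are reduced by PCA
#' (dimensionality chosen by tenfold cross-validation unless given),
#' projected onto Fisher discriminant axes, and the combined projection is
#' orthonormalised by QR so that within-subspace Euclidean geometry is
#' preserved. Each trial ends up as a point in a (C-1)-dimensional space.
#'
#' @param nkt a z-scored [NKTDataset-class] (see [zscorePerNeuron()]),
#'   aligned so that the window below is covered.
#' @param labels condition label per trial (defaults to the first-reach
#'   direction).
#' @param trialsSubset logical or integer index of trials used to fit the
#'   subspace (default all).
#' @param window feature window in ms relative to the dataset alignment
#'   (default `c(-600, 0)`, the preparatory period before GO for
#'   GO-aligned data).
#' @param binWidth coarse bin width in ms (default 300).
#' @param nPCs number of PCs; `NULL` chooses by cross-validation.
#' @param folds CV folds for the PC choice.
#' @param seed seed for the CV fold assignment.
#' @return a [StateEmbedding-class]; explained variance is reported per
#'   basis column as the variance of the projected training data over the
#'   total feature variance, sorted decreasingly.
#' @export
fitSubspace <- function(nkt, labels = NULL, trialsSubset = NULL,
                        window = c(-600, 0), binWidth = 300,
                        nPCs = NULL, folds = 10, seed = 1L) {
  stopifnot(is(nkt, "NKTDataset"))
  tr <- trialTable(nkt)
  if (is.null(labels)) labels <- tr$theta1
  labels <- as.factor(labels)
  if (is.null(trialsSubset)) trialsSubset <- seq_len(nrow(tr))
  feat <- .trialFeatures(nkt, window, binWidth)
  X <- feat[trialsSubset, , drop = FALSE]
  lab <- droplevels(labels[trialsSubset])
  if (nrow(X) < nlevels(lab)) stop("fewer trials than classes")

  mu <- colMeans(X)
  scl <- rep(1, ncol(X))
  Xc <- sweep(X, 2, mu)
  if (is.null(nPCs))
    nPCs <- chooseNumPCs(Xc, lab, folds = folds, seed = seed)$P
  nPCs <- min(nPCs, ncol(Xc), nrow(Xc) - 1L)
  sv <- svd(Xc, nu = 0, nv = nPCs)
  V <- sv$v                                  # features x P
  S <- Xc %*% V
  A <- .fisherLDA(S, lab)                    # P x (C-1)
  Wfull <- V %*% A                           # features x (C-1)
  qrW <- qr(Wfull)
  Q <- qr.Q(qrW)[, seq_len(ncol(Wfull)), drop = FALSE]
  for (j in seq_len(ncol(Q))) {              # deterministic sign
    i <- which.max(abs(Q[, j]))
    if (Q[i, j] < 0) Q[, j] <- -Q[, j]
  }
  states <- Xc %*% Q
  totVar <- sum(apply(Xc, 2, stats::var))
  ev <- apply(states, 2, stats::var) / totVar
  o <- order(ev, decreasing = TRUE)
  Q <- Q[, o, drop = FALSE]
  states <- states[, o, drop = FALSE]
  ev <- ev[o]

  new("StateEmbedding", basis = Q, pcaBasis = V, ldaAxes = A,
      center = mu, scale = scl, states = states, labels = lab,
      explainedVariance = ev, nPCs = as.integer(nPCs))
}

#' Project trials into a fitted state embedding
#'
#' Projects held-out trials into the fixed orthonormal basis of a
#' [StateEmbedding-class] without refitting (e.g. projecting double-reach
#' trials onto the single-reach subspace).
#'
#' @param embedding a [StateEmbedding-class] from [fitSubspace()].
#' @param nkt an [NKTDataset-class] with the same neurons, z-scored the
#'   same way.
#' @param trialsSubset optional trial subset.
#' @param window,binWidth the feature window; must match the fit.
#' @return matrix of trial states (trials x (C-1)).
#' @export
projectStates <- function(embedding, nkt, trialsSubset = NULL,
                          window = c(-600, 0), binWidth = 300) {
  stopifnot(is(embedding, "StateEmbedding"), is(nkt, "NKTDataset"))
  feat <- .trialFeatures(nkt, window, binWidth)
  if (ncol(feat) != nrow(embedding@basis))
    stop("feature dimension mismatch: embedding was fitted on a different ",
         "neuron set or window")
  if (!is.null(trialsSubset)) feat <- feat[trialsSubset, , drop = FALSE]
  sweep(feat, 2, embedding@center) %*% embedding@basis
}

#' Cluster geometry of embedded states
#'
#' Per-label means and covariances of trial states, plus pairwise
#' Mahalanobis distances between cluster means computed with the pooled
#' within-class covariance (symmetric by construction). A singular pooled
#' covariance gets a small ridge, with a message.
#'
#' @param states trials x dims state matrix.
#' @param labels label per trial (at least 3 trials each).
#' @return list with `means` (labels x dims), `covariances` (list),
#'   `mahalanobis` (symmetric distance matrix, zero diagonal).
#' @export
clusterGeometry <- function(states, labels) {
  labels <- droplevels(as.factor(labels))
  states <- as.matrix(states)
  if (min(table(labels)) < 3) stop("need at least 3 trials per label")
  classes <- levels(labels)
  d <- ncol(states)
  means <- t(sapply(classes, function(cl)
    colMeans(states[labels == cl, , drop = FALSE])))
  covs <- lapply(classes, function(cl)
    stats::cov(states[labels == cl, , drop = FALSE]))
  names(covs) <- classes
  pooled <- matrix(0, d, d)
  for (cl in classes) {
    ni <- sum(labels == cl)
    pooled <- pooled + (ni - 1) * covs[[cl]]
  }
  pooled <- pooled / (nrow(states) - length(classes))
  if (rcond(pooled) < 1e-12) {
    message("singular pooled covariance: adding ridge")
    pooled <- pooled + 1e-8 * mean(diag(pooled) + 1) * diag(d)
  }
  Pinv <- solve(pooled)
  D <- matrix(0, length(classes), length(classes),
              dimnames = list(classes, classes))
  for (i in seq_along(classes)) for (j in seq_along(classes)) {
    if (i < j) {
      v <- means[i, ] - means[j, ]
      D[i, j] <- D[j, i] <- sqrt(drop(t(v) %*% Pinv %*% v))
    }
  }
  list(means = means, covariances = covs, mahalanobis = D)
}

#' Sliding-window LDA decoding with permutation chance band
#'
#' Trains LDA decoders on z-scored rates in a sliding window and reports
#' stratified k-fold cross-validated accuracy per bin, together with a
#' chance band obtained by shuffling trial labels (100 shuffles by
#' default, band = the given quantiles of shuffled accuracies).
#'
#' @param nkt a z-scored [NKTDataset-class].
#' @param target `"theta1"` or `"theta21"`, or a vector of labels.
#' @param binWidth,step sliding window in ms (defaults 300 and 20).
#' @param folds CV folds (reduced with a warning if a class has fewer
#'   trials).
#' @param nShuffle label shuffles for the chance band.
#' @param nPCs PCs retained inside each decoder fold (default
#'   `min(20, features)`), guarding LDA against singular scatter.
#' @param probs quantiles of the shuffle distribution for the band.
#' @param seed integer seed.
#' @return data.frame per bin: `binCenter`, `accuracy`, `chanceLo`,
#'   `chanceMedian`, `chanceHi`, `nShuffle`.
#' @export
slidingWindowDecode <- function(nkt, target = "theta1", binWidth = 300,
                                step = 20, folds = 10, nShuffle = 100,
                                nPCs = NULL, probs = c(0.025, 0.975),
                                seed = 1L) {
  stopifnot(is(nkt, "NKTDataset"))
  tr <- trialTable(nkt)
  labels <- if (is.character(target) && length(target) == 1 &&
                target %in% names(tr)) tr[[target]] else target
  if (anyNA(labels)) stop("labels unavailable for some trials")
  labels <- droplevels(as.factor(labels))
  minClass <- min(table(labels))
  if (minClass < folds) {
    warning("reducing folds to smallest class size (", minClass, ")")
    folds <- minClass
  }
  rs <- .restoreSeed(seed)
  on.exit(rs())

  bc <- binCenters(nkt)
  span <- range(bc)
  centers <- seq(span[1] + binWidth / 2, span[2] - binWidth / 2, by = step)
  if (length(centers) == 0) stop("recorded span narrower than binWidth")
  arr <- rates(nkt)
  N <- dim(arr)[1]
  if (is.null(nPCs)) nPCs <- min(20L, N)

  shuffles <- replicate(nShuffle, sample(labels), simplify = FALSE)
  res <- lapply(centers, function(ct) {
    sel <- bc >= ct - binWidth / 2 & bc < ct + binWidth / 2
    X <- t(apply(arr[, , sel, drop = FALSE], c(1, 2), mean))  # K x N
    acc <- .cvAccuracy(X, labels, nPCs, folds)
    shacc <- vapply(shuffles, function(sl) .cvAccuracy(X, sl, nPCs, folds),
                    numeric(1))
    q <- stats::quantile(shacc, probs, names = FALSE)
    data.frame(binCenter = ct, accuracy = acc, chanceLo = q[1],
               chanceMedian = stats::median(shacc), chanceHi = q[2],
               nShuffle = nShuffle)
  })
  do.call(rbind, res)
}
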