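# Shared builders for synthetic fixtures; everything is generated in code.

# Double-reach condition grid of the multi-angle task (30 DR conditions)
drConditions <- function() {
  cfg <- makeTaskConfig("multi_angle", trialsPerCondition = 1)
  cfg$conditions[cfg$conditions$type == "DR", , drop = FALSE]
}

# Evaluate a joint tuning model (full parameterisation; set unused terms 0)
jointModelResponse <- function(theta1, theta21, a1 = 0, a2 = 0, b = 0,
                               c = 0, thetaPD = 0) {
  c1 <- cos((theta1 - thetaPD) * pi / 180)
  c2 <- cos((theta21 - thetaPD) * pi / 180)
  a1 * c1 + a2 * c2 + b * c1 * c2 + c
}

# NKTDataset of pure noise over the 30 DR conditions (one trial each)
noiseNKT <- function(nNeurons, nBins, sd = 0.1, seed = 1) {
  set.seed(seed)
  cfg <- makeTaskConfig("multi_angle", trialsPerCondition = 1, seed = seed)
  trials <- generateTrials(cfg)
  trials <- trials[trials$type == "DR", , drop = FALSE]
  trials$trial <- seq_len(nrow(trials))
  arr <- array(rnorm(nNeurons * nrow(trials) * nBins, 0, sd),
               c(nNeurons, nrow(trials), nBins))
  new("NKTDataset", rates = arr, binCenters = seq_len(nBins) * 20,
      alignment = "MO", trials = trials,
      neuronMeta = data.frame(row.names = seq_len(nNeurons)))
}

# Population whose condition-mean responses follow a given scheme
# ("multiplicative" = a2 == 0, "additive" = b == 0, "full" = both terms),
# with trial noise.
tunedPopulation <- function(nNeurons, scheme, noiseSD = 0.05,
                            trialsPerCondition = 1, seed = 1) {
  set.seed(seed)
  truth <- data.frame(
    a1 = runif(nNeurons, 0.3, 0.7),
    a2 = if (scheme %in% c("additive", "full"))
      runif(nNeurons, 0.3, 0.7) else 0,
    b  = if (scheme %in% c("multiplicative", "full"))
      runif(nNeurons, 0.3, 0.7) else 0,
    c  = runif(nNeurons, 0.2, 0.5),
    thetaPD = runif(nNeurons, 0, 360))
  cfg <- makeTaskConfig("multi_angle",
                        trialsPerCondition = trialsPerCondition,
                        seed = seed)
  generatePopulationDataset(nNeurons, "full", cfg, seed = seed,
                            truth = truth, window = c(0, 0), dt = 50,
                            noiseSD = noiseSD)
}

# Condition-mean responses (conditions x neurons) of an NKT's DR trials
# at a single bin
conditionMeans <- function(nkt, bin = 1) {
  tr <- trialTable(nkt)
  keep <- tr$type == "DR"
  arr <- rates(nkt)[, keep, bin, drop = FALSE]
  tr <- tr[keep, , drop = FALSE]
  ids <- interaction(tr$theta1, tr$theta21, drop = TRUE)
  lv <- levels(ids)
  Y <- sapply(lv, function(l) rowMeans(arr[, ids == l, 1, drop = FALSE]))
  first <- match(lv, ids)
  list(Y = t(Y), theta1 = tr$theta1[first], theta21 = tr$theta21[first])
}

# Well-separated Gaussian class clusters in `info` informative dimensions
# embedded in `noise` noise dimensions
clusteredData <- function(nPerClass = 20, classes = 6, info = 2,
                          noise = 30, sep = 6, sd = 1, seed = 1) {
  set.seed(seed)
  lab <- rep(seq_len(classes), each = nPerClass)
  ang <- 2 * pi * (lab - 1) / classes
  X <- cbind(sep * cos(ang), sep * sin(ang))[, seq_len(min(2, info)),
                                             drop = FALSE]
  if (info > 2) X <- cbind(X, matrix(0, length(lab), info - 2))
  X <- X + matrix(rnorm(length(lab) * info, 0, sd), ncol = info)
  X <- cbind(X, matrix(rnorm(length(lab) * noise), ncol = noise))
  list(X = X, labels = factor(lab))
}
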