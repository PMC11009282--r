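#' Analysis epoch definitions
#'
#' Named task epochs used by the sequence-selectivity census and tuning
#' summaries, as windows relative to an event marker: `preparatory` is the
#' 600 ms before GO, `pre_movement` the 200 ms before MO, `peri_movement`
#' the 200 ms before ME, `peri_MO` is -100 to 100 ms around MO, and
#' `peri_ME` is 100 to 300 ms after MO.
#'
#' @param name epoch name.
#' @return list with `name`, `window` (start/end ms) and `marker`.
#' @export
epochSpec <- function(name = c("preparatory", "pre_movement", "peri_movement",
                               "peri_MO", "peri_ME")) {
  name <- match.arg(name)
  spec <- switch(name,
    preparatory   = list(window = c(-600, 0),  marker = "GO"),
    pre_movement  = list(window = c(-200, 0),  marker = "MO"),
    peri_movement = list(window = c(-200, 0),  marker = "ME"),
    peri_MO       = list(window = c(-100, 100), marker = "MO"),
    peri_ME       = list(window = c(100, 300), marker = "MO"))
  c(list(name = name), spec)
}

#' Peri-stimulus time histogram
#'
#' Trial-averaged firing-rate estimate from spike times, aligned to an
#' event marker and smoothed with a Gaussian kernel (SD 20 ms by default).
#' The standard-error band is estimated by bootstrap resampling of trials
#' (10 samples by default).
#'
#' @param spikes list with one numeric vector of spike times (ms) per
#'   trial.
#' @param alignTimes numeric vector of marker times (ms), one per trial.
#' @param window c(start, end) ms relative to the marker.
#' @param kernelSD Gaussian kernel SD in ms.
#' @param nBoot bootstrap samples for the SE band.
#' @param dt output grid spacing in ms.
#' @param seed seed for the bootstrap.
#' @return data.frame with `time` (ms), `rate` (spikes/s) and `se`;
#'   attributes `alignment` window and `kernelSD` are recorded.
#' @export
computePSTH <- function(spikes, alignTimes, window = c(-500, 500),
                        kernelSD = 20, nBoot = 10, dt = 1, seed = 1L) {
  nTrials <- length(spikes)
  if (nTrials == 0) stop("no trials")
  stopifnot(length(alignTimes) == nTrials)
  grid <- seq(window[1], window[2], by = dt)

  trialRate <- function(s, align) {
    s <- s - align
    s <- s[s >= window[1] - 5 * kernelSD & s <= window[2] + 5 * kernelSD]
    if (length(s) == 0) return(numeric(length(grid)))
    # sum of Gaussian bumps, spikes/ms -> spikes/s
    1000 * rowSums(sapply(s, function(sp) stats::dnorm(grid, sp, kernelSD)))
  }
  mat <- mapply(trialRate, spikes, alignTimes)      # grid x trials
  mat <- matrix(mat, nrow = length(grid))
  rate <- rowMeans(mat)

  rs <- .restoreSeed(seed)
  on.exit(rs())
  if (all(mat == 0)) {
    se <- numeric(length(grid))
  } else {
    boot <- replicate(nBoot, {
      rowMeans(mat[, sample.int(nTrials, replace = TRUE), drop = FALSE])
    })
    se <- apply(boot, 1, stats::sd)
  }
  out <- data.frame(time = grid, rate = rate, se = se)
  attr(out, "kernelSD") <- kernelSD
  attr(out, "window") <- window
  out
}

#' Re-bin a dataset with sliding windows
#'
#' Re-bins the rate tensor of an [NKTDataset-class] into overlapping
#' sliding windows: each output bin is the mean rate over
#' `[center - binWidth/2, center + binWidth/2)`. Bins whose edges fall
#' outside the recorded span are dropped, not zero-padded.
#'
#' @param nkt an [NKTDataset-class] on a finer time grid.
#' @param binWidth window width in ms (default 200).
#' @param step window step in ms (default 20; a step larger than the width
#'   leaves gaps and warns).
#' @param window c(start, end) ms to cover (default the recorded span).
#' @return a new [NKTDataset-class] with sliding-window bin centers.
#' @export
assembleNKT <- function(nkt, binWidth = 200, step = 20, window = NULL) {
  stopifnot(is(nkt, "NKTDataset"))
  if (step > binWidth) warning("step > binWidth leaves unsampled gaps")
  bc <- binCenters(nkt)
  span <- range(bc)
  if (is.null(window)) window <- span
  if (window[1] < span[1] - 1e-9 || window[2] > span[2] + 1e-9)
    stop("window extends outside the recorded span")
  centers <- seq(window[1] + binWidth / 2, window[2] - binWidth / 2,
                 by = step)
  if (length(centers) == 0)
    stop("window narrower than binWidth: no complete bins")
  arr <- rates(nkt)
  out <- array(0, dim = c(dim(arr)[1], dim(arr)[2], length(centers)))
  for (i in seq_along(centers)) {
    sel <- bc >= centers[i] - binWidth / 2 & bc < centers[i] + binWidth / 2
    # right-closed fallback for the final grid point
    if (!any(sel)) sel <- abs(bc - centers[i]) <= binWidth / 2
    out[, , i] <- apply(arr[, , sel, drop = FALSE], c(1, 2), mean)
  }
  methods::initialize(nkt, rates = out, binCenters = centers)
}

#' Normalise rates for tuning regression
#'
#' Per-neuron max-normalisation used before tuning regression: every rate
#' is divided by the maximum of the condition-averaged rate over all
#' conditions and bins, plus a softening floor `epsilon` that keeps
#' near-silent neurons from exploding. All-zero neurons are left at zero
#' and flagged.
#'
#' @param nkt an [NKTDataset-class].
#' @param epsilon softening floor in the rate units (default 5, i.e. 5
#'   spikes/s for spike-derived rates; use a smaller value for unit-scale
#'   surrogate activations).
#' @return the dataset with normalised rates; `neuronMeta` gains
#'   `normFactor` (the divisor) and `allZero` columns.
#' @export
normalizeForRegression <- function(nkt, epsilon = 5) {
  stopifnot(is(nkt, "NKTDataset"))
  arr <- rates(nkt)
  tr <- trialTable(nkt)
  # NA second-reach angles (SR trials) must still form valid conditions
  th21 <- ifelse(is.na(tr$theta21), -1, tr$theta21)
  condIds <- interaction(tr$type, tr$theta1, th21, drop = TRUE)
  N <- dim(arr)[1]
  peak <- numeric(N)
  for (l in levels(condIds)) {
    m <- condIds == l
    cm <- apply(arr[, m, , drop = FALSE], c(1, 3), mean)   # N x T
    peak <- pmax(peak, apply(matrix(cm, nrow = N), 1, max))
  }
  allZero <- apply(arr, 1, function(x) all(x == 0))
  fac <- peak + epsilon
  out <- arr / fac     # recycles over first dimension
  meta <- neuronMeta(nkt)
  if (nrow(meta) == 0) meta <- data.frame(row.names = seq_len(N))
  meta$normFactor <- fac
  meta$allZero <- allZero
  methods::initialize(nkt, rates = out, neuronMeta = meta)
}

#' Z-score rates per neuron
#'
#' Centers and scales each neuron's rates to mean 0 and SD 1 across all
#' trials and bins (the normalisation used before PCA-LDA state-space
#' analysis). Zero-variance neurons cannot be scaled and are excluded with
#' a message.
#'
#' @param nkt an [NKTDataset-class].
#' @return the dataset with z-scored rates (possibly fewer neurons);
#'   excluded neuron indices are kept in `attr(, "excluded")`.
#' @export
zscorePerNeuron <- function(nkt) {
  stopifnot(is(nkt, "NKTDataset"))
  arr <- rates(nkt)
  N <- dim(arr)[1]
  mu <- apply(arr, 1, mean)
  sd1 <- apply(arr, 1, stats::sd)
  bad <- sd1 == 0 | !is.finite(sd1)
  if (any(bad))
    message("excluding ", sum(bad), " zero-variance neuron(s): ",
            paste(which(bad), collapse = ", "))
  keep <- which(!bad)
  if (length(keep) == 0) stop("no neurons with non-zero variance")
  out <- (arr[keep, , , drop = FALSE] - mu[keep]) / sd1[keep]
  meta <- neuronMeta(nkt)
  if (nrow(meta) > 0) meta <- meta[keep, , drop = FALSE]
  res <- methods::initialize(nkt, rates = out, neuronMeta = meta)
  attr(res, "excluded") <- which(bad)
  res
}

# Per-trial epoch-mean rates (neurons x trials) for an epoch that may be
# anchored to a different marker than the dataset alignment.
.epochMeans <- function(nkt, epoch) {
  tr <- trialTable(nkt)
  bc <- binCenters(nkt)
  arr <- rates(nkt)
  align <- alignmentMarker(nkt)
  if (!epoch$marker %in% names(tr))
    stop("epoch marker '", epoch$marker, "' not in the trial table")
  offset <- tr[[epoch$marker]] - tr[[align]]
  if (anyNA(offset))
    stop("epoch '", epoch$name, "' undefined for some trials (marker '",
         epoch$marker, "' is NA)")
  N <- dim(arr)[1]; K <- dim(arr)[2]
  out <- matrix(NA_real_, N, K)
  for (k in seq_len(K)) {
    lo <- epoch$window[1] + offset[k]
    hi <- epoch$window[2] + offset[k]
    sel <- bc >= lo & bc < hi
    if (!any(sel)) sel <- which.min(abs(bc - (lo + hi) / 2))
    out[, k] <- rowMeans(arr[, k, sel, drop = FALSE])
  }
  out
}

#' Sequence-selectivity census
#'
#' For each neuron, compares epoch-mean rates between two trial groups with
#' a two-sided Wilcoxon rank-sum test and reports the proportion of neurons
#' significant at `alpha`. Contrasts: `"SR_vs_DR"` (single vs double
#' reach) and `"CW_vs_CCW"` (clockwise vs counterclockwise second-target
#' displacement among DR trials; 180-deg displacements belong to neither
#' group and are dropped).
#'
#' @param nkt an [NKTDataset-class] of trial-resolved rates.
#' @param epoch an epoch from [epochSpec()] (or a compatible list).
#' @param contrast `"SR_vs_DR"` or `"CW_vs_CCW"`.
#' @param alpha significance threshold (default 0.05).
#' @return list with `proportion` (significant fraction), `pValues`
#'   (per neuron), and `groups` (trial counts per group).
#' @export
selectivityCensus <- function(nkt, epoch = epochSpec("preparatory"),
                              contrast = c("SR_vs_DR", "CW_vs_CCW"),
                              alpha = 0.05) {
  contrast <- match.arg(contrast)
  tr <- trialTable(nkt)
  if (contrast == "SR_vs_DR") {
    g1 <- tr$type == "SR"; g2 <- tr$type == "DR"
  } else {
    disp <- angleDiff(tr$theta2, tr$theta1)
    g1 <- tr$type == "DR" & !is.na(disp) & disp < 0 & disp > -180   # CW
    g2 <- tr$type == "DR" & !is.na(disp) & disp > 0 & disp < 180    # CCW
  }
  if (!any(g1) || !any(g2))
    stop("contrast '", contrast, "' needs trials in both groups")
  em <- .epochMeans(nkt, epoch)
  p <- apply(em, 1, function(x) {
    if (all(x[g1] == x[g1][1]) && all(x[g2] == x[g2][1]) &&
        x[g1][1] == x[g2][1]) return(1)
    stats::wilcox.test(x[g1], x[g2], exact = FALSE)$p.value
  })
  list(proportion = mean(p < alpha), pValues = p,
       groups = c(sum(g1), sum(g2)))
}
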