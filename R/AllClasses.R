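#' @import methods
NULL

#' Trial-resolved rate tensor with trial metadata
#'
#' Container for a neurons x trials x time-bins rate tensor ("NKT" layout)
#' together with its bin grid, the event marker the bins are aligned to, the
#' per-trial condition/event table, and optional per-neuron metadata (e.g.
#' ground-truth tuning parameters of a surrogate population).
#'
#' @slot rates numeric array, neurons x trials x bins (spikes/s or
#'   dimensionless surrogate activations).
#' @slot binCenters numeric vector of bin centers in ms, relative to
#'   `alignment`.
#' @slot alignment name of the event marker at time zero (e.g. `"MO"`).
#' @slot trials data.frame with one row per trial: `type` ("SR"/"DR"),
#'   `theta1`, `theta2`, `theta21` (deg; NA for SR), and event times in ms
#'   (`TO`, `GO`, `MO`, `ME`, `MO2`, `ME2`).
#' @slot neuronMeta data.frame with one row per neuron (may have zero
#'   columns); for surrogate data holds `thetaPD`, latency `tau`, and any
#'   ground-truth coefficients.
#'
#' @seealso [generatePopulationDataset()], [assembleNKT()]
#' @export
setClass("NKTDataset",
  representation(
    rates      = "array",
    binCenters = "numeric",
    alignment  = "character",
    trials     = "data.frame",
    neuronMeta = "data.frame"
  )
)

setValidity("NKTDataset", function(object) {
  d <- dim(object@rates)
  msgs <- character(0)
  if (length(d) != 3L)
    msgs <- c(msgs, "rates must be a 3-D array (neurons x trials x bins)")
  else {
    if (d[2L] != nrow(object@trials))
      msgs <- c(msgs, sprintf("trial dimension (%d) != rows of trials (%d)",
                              d[2L], nrow(object@trials)))
    if (d[3L] != length(object@binCenters))
      msgs <- c(msgs, sprintf("bin dimension (%d) != length(binCenters) (%d)",
                              d[3L], length(object@binCenters)))
    if (nrow(object@neuronMeta) > 0L && nrow(object@neuronMeta) != d[1L])
      msgs <- c(msgs, "neuronMeta rows must match neuron dimension")
  }
  if (anyNA(object@rates))
    msgs <- c(msgs, "rates must not contain NA/NaN")
  if (length(object@alignment) != 1L)
    msgs <- c(msgs, "alignment must be a single marker name")
  if (length(msgs)) msgs else TRUE
})

#' PCA-LDA-QR embedding of trial states
#'
#' Result of the supervised dimensionality reduction used for preparatory
#' neural states: z-scored trial vectors are reduced by PCA (number of
#' components chosen by cross-validation), projected by Fisher LDA, and the
#' combined projection is orthonormalised by QR. Each trial becomes a point
#' in a (C-1)-dimensional space for C condition labels.
#'
#' @slot basis orthonormal projection matrix (features x (C-1)).
#' @slot pcaBasis PCA loading matrix (features x P).
#' @slot ldaAxes discriminant axes in PCA coordinates (P x (C-1)).
#' @slot center,scale per-feature z-scoring parameters of the training data.
#' @slot states training-trial states (trials x (C-1)).
#' @slot labels factor of training labels.
#' @slot explainedVariance fraction of total training variance captured by
#'   each basis column, sorted so displayed dimensions come first.
#' @slot nPCs number of principal components retained.
#'
#' @seealso [fitSubspace()], [projectStates()]
#' @export
setClass("StateEmbedding",
  representation(
    basis             = "matrix",
    pcaBasis          = "matrix",
    ldaAxes           = "matrix",
    center            = "numeric",
    scale             = "numeric",
    states            = "matrix",
    labels            = "factor",
    explainedVariance = "numeric",
    nPCs              = "integer"
  )
)

setValidity("StateEmbedding", function(object) {
  msgs <- character(0)
  if (nrow(object@states) != length(object@labels))
    msgs <- c(msgs, "states rows must match labels")
  if (ncol(object@basis) != ncol(object@states))
    msgs <- c(msgs, "basis columns must match state dimensions")
  g <- crossprod(object@basis)
  if (max(abs(g - diag(ncol(g)))) > 1e-10)
    msgs <- c(msgs, "basis columns must be orthonormal (tolerance 1e-10)")
  if (length(msgs)) msgs else TRUE
})

#' Continuous-time recurrent network model
#'
#' Rate-based recurrent network with rectified-tanh units evolving as
#' `tau * dx/dt = -x + J r + B u`, read out linearly as `z = W r`.
#'
#' @slot J internal connectivity (N x N).
#' @slot B input weights (N x I), I = 5 input channels.
#' @slot W readout weights (2 x N).
#' @slot tau membrane time constant in ms.
#' @slot g internal weight scale used at initialisation.
#' @slot dt Euler integration step in ms.
#' @slot history training history (iteration, loss, mse, r2); zero rows for
#'   an untrained network.
#' @slot config list of training settings (learning rate, iterations,
#'   regularisation weight, seed, timing).
#'
#' @seealso [initRNN()], [trainRNN()], [simulateRNN()]
#' @export
setClass("RNNModel",
  representation(
    J       = "matrix",
    B       = "matrix",
    W       = "matrix",
    tau     = "numeric",
    g       = "numeric",
    dt      = "numeric",
    history = "data.frame",
    config  = "list"
  )
)

setValidity("RNNModel", function(object) {
  msgs <- character(0)
  N <- nrow(object@J)
  if (ncol(object@J) != N) msgs <- c(msgs, "J must be square")
  if (nrow(object@B) != N) msgs <- c(msgs, "B rows must match network size")
  if (ncol(object@W) != N) msgs <- c(msgs, "W columns must match network size")
  if (object@tau <= 0) msgs <- c(msgs, "tau must be positive")
  if (object@dt > object@tau / 2)
    msgs <- c(msgs, "integration step dt must satisfy dt <= tau/2")
  if (length(msgs)) msgs else TRUE
})

#' Single tuning-model fit
#'
#' Per-neuron, per-time-bin fit of one of the directional tuning models
#' (single cosine in theta1/theta2/theta21 coordinates, additive,
#' multiplicative, or full). The shared preferred direction is profiled on a
#' degree grid and the remaining coefficients are solved by least squares.
#'
#' @slot model model name.
#' @slot a1,a2,b,c fitted coefficients (NA for terms absent from the model).
#' @slot thetaPD fitted preferred direction, deg in [0, 360).
#' @slot r2 plain coefficient of determination.
#' @slot r2adj adjusted R-squared penalised for the coefficient count.
#' @slot n number of observations used in the fit.
#' @slot p number of fitted parameters (3 cosine, 4 additive/multiplicative,
#'   5 full; the preferred direction counts as a parameter).
#' @slot sse,sst residual and total sums of squares.
#' @slot binCenter bin center in ms (NA when not a sliding-window fit).
#' @slot flags character vector of diagnostic flags ("constant", "aliased",
#'   ...).
#' @export
setClass("TuningFit",
  representation(
    model     = "character",
    a1        = "numeric",
    a2        = "numeric",
    b         = "numeric",
    c         = "numeric",
    thetaPD   = "numeric",
    r2        = "numeric",
    r2adj     = "numeric",
    n         = "integer",
    p         = "integer",
    sse       = "numeric",
    sst       = "numeric",
    binCenter = "numeric",
    flags     = "character"
  )
)

setMethod("show", "NKTDataset", function(object) {
  d <- dim(object@rates)
  cat("NKTDataset:", d[1L], "neurons x", d[2L], "trials x", d[3L], "bins\n")
  cat("  aligned to", object@alignment, "| bins",
      sprintf("[%g, %g] ms", min(object@binCenters), max(object@binCenters)),
      "\n")
  tt <- table(object@trials$type)
  cat("  trials:", paste(sprintf("%s=%d", names(tt), tt), collapse = ", "),
      "\n")
  if (ncol(object@neuronMeta) > 0L)
    cat("  neuronMeta:", paste(colnames(object@neuronMeta), collapse = ", "),
        "\n")
  invisible(object)
})

setMethod("show", "StateEmbedding", function(object) {
  cat("StateEmbedding:", nrow(object@states), "trials in",
      ncol(object@states), "dimensions (", object@nPCs, "PCs )\n")
  cat("  explained variance (top 2):",
      paste(sprintf("%.1f%%", 100 * utils::head(object@explainedVariance, 2)),
            collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "RNNModel", function(object) {
  cat("RNNModel:", nrow(object@J), "nodes, tau =", object@tau,
      "ms, dt =", object@dt, "ms\n")
  if (nrow(object@history) > 0L) {
    last <- object@history[nrow(object@history), ]
    cat(sprintf("  trained %d iterations: MSE = %.4f, R2 = %.3f\n",
                last$iteration, last$mse, last$r2))
  } else cat("  untrained\n")
  invisible(object)
})

setMethod("show", "TuningFit", function(object) {
  cat("TuningFit [", object@model, "] thetaPD =",
      sprintf("%.1f deg;", object@thetaPD),
      "R2adj =", sprintf("%.3f", object@r2adj), "\n")
  co <- c(a1 = object@a1, a2 = object@a2, b = object@b, c = object@c)
  co <- co[!is.na(co)]
  cat("  ", paste(sprintf("%s = %.4f", names(co), co), collapse = ", "), "\n")
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
  invisible(object)
})
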