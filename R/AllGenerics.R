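#' Accessors for NKTDataset and related containers
#'
#' @param x an object.
#' @param ... unused.
#' @return `rates()` the neurons x trials x bins array; `trialTable()` the
#'   per-trial condition/event data.frame; `binCenters()` the bin grid in ms;
#'   `neuronMeta()` the per-neuron metadata data.frame; `alignmentMarker()`
#'   the name of the event at time zero.
#' @examples
#' cfg <- makeTaskConfig("standard", trialsPerCondition = 2, seed = 1)
#' nkt <- generatePopulationDataset(4, "cosine", cfg, seed = 1)
#' dim(rates(nkt)); head(trialTable(nkt))
#' @name nkt-accessors
NULL

#' @rdname nkt-accessors
#' @export
setGeneric("rates", function(x, ...) standardGeneric("rates"))
#' @rdname nkt-accessors
#' @export
setGeneric("trialTable", function(x, ...) standardGeneric("trialTable"))
#' @rdname nkt-accessors
#' @export
setGeneric("binCenters", function(x, ...) standardGeneric("binCenters"))
#' @rdname nkt-accessors
#' @export
setGeneric("neuronMeta", function(x, ...) standardGeneric("neuronMeta"))
#' @rdname nkt-accessors
#' @export
setGeneric("alignmentMarker", function(x, ...) standardGeneric("alignmentMarker"))

#' @rdname nkt-accessors
#' @export
setMethod("rates", "NKTDataset", function(x, ...) x@rates)
#' @rdname nkt-accessors
#' @export
setMethod("trialTable", "NKTDataset", function(x, ...) x@trials)
#' @rdname nkt-accessors
#' @export
setMethod("binCenters", "NKTDataset", function(x, ...) x@binCenters)
#' @rdname nkt-accessors
#' @export
setMethod("neuronMeta", "NKTDataset", function(x, ...) x@neuronMeta)
#' @rdname nkt-accessors
#' @export
setMethod("alignmentMarker", "NKTDataset", function(x, ...) x@alignment)

#' Coerce a TuningFit to a one-row data.frame
#'
#' @param x a [TuningFit-class] object.
#' @param row.names,optional,... passed through for compatibility.
#' @return one-row data.frame with model, coefficients, thetaPD, fit
#'   diagnostics and flags.
#' @export
as.data.frame.TuningFit <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    model = x@model, a1 = x@a1, a2 = x@a2, b = x@b, c = x@c,
    thetaPD = x@thetaPD, r2 = x@r2, r2adj = x@r2adj,
    n = x@n, p = x@p, sse = x@sse, sst = x@sst,
    binCenter = x@binCenter,
    flags = paste(x@flags, collapse = ";"),
    stringsAsFactors = FALSE
  )
}
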