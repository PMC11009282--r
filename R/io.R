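#' Export / import an NKTDataset as plain-text files
#'
#' Writes the rate tensor as a wide CSV (one row per neuron x trial, one
#' column per bin), the trial table as CSV, and a JSON sidecar holding the
#' dimensions, bin centers, alignment marker and neuron metadata.
#' `importNKT()` reads the same layout back.
#'
#' @param nkt an [NKTDataset-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return `exportNKT()` the directory, invisibly; `importNKT()` the
#'   reconstructed [NKTDataset-class].
#' @export
exportNKT <- function(nkt, dir, prefix = "nkt") {
  stopifnot(is(nkt, "NKTDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arr <- rates(nkt)
  d <- dim(arr)
  flat <- matrix(aperm(arr, c(2, 1, 3)), d[1] * d[2], d[3])
  ratesFile <- file.path(dir, paste0(prefix, "_rates.csv"))
  utils::write.csv(flat, ratesFile, row.names = FALSE)
  utils::write.csv(trialTable(nkt),
                   file.path(dir, paste0(prefix, "_trials.csv")),
                   row.names = FALSE)
  meta <- list(dims = d, binCenters = binCenters(nkt),
               alignment = alignmentMarker(nkt),
               neuronMeta = neuronMeta(nkt))
  jsonlite::write_json(meta, file.path(dir, paste0(prefix, "_meta.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname exportNKT
#' @export
importNKT <- function(dir, prefix = "nkt") {
  meta <- jsonlite::read_json(file.path(dir, paste0(prefix, "_meta.json")),
                              simplifyVector = TRUE)
  d <- as.integer(meta$dims)
  flat <- as.matrix(utils::read.csv(
    file.path(dir, paste0(prefix, "_rates.csv"))))
  arr <- aperm(array(flat, c(d[2], d[1], d[3])), c(2, 1, 3))
  trials <- utils::read.csv(file.path(dir, paste0(prefix, "_trials.csv")))
  nm <- as.data.frame(meta$neuronMeta)
  new("NKTDataset", rates = arr, binCenters = as.numeric(meta$binCenters),
      alignment = meta$alignment, trials = trials, neuronMeta = nm)
}
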