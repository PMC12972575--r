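#' Selection frequencies of a stability-selection result
#'
#' @param object a [StabilityResult-class].
#' @return data.frame with columns gene, frequency, meanNonzeroCoef, sorted by
#'   frequency descending then gene id.
#' @export
setGeneric("selectionFrequencies", function(object) {
  standardGeneric("selectionFrequencies")
})

#' Stable gene set above a selection-frequency threshold
#'
#' Genes whose bootstrap selection frequency strictly exceeds `threshold`,
#' ranked by frequency descending with ties broken by gene id.
#'
#' @param object a [StabilityResult-class] or a data.frame with columns
#'   gene and frequency.
#' @param threshold frequency cutoff in \[0, 1\]; default 0.5.
#' @return character vector of gene ids, ranked.
#' @export
setGeneric("stableSet", function(object, threshold = 0.5) {
  standardGeneric("stableSet")
})

#' @export
setGeneric("penalty", function(object) standardGeneric("penalty"))

setMethod("selectionFrequencies", "StabilityResult", function(object) {
  rec <- object@records
  rec[order(-rec$frequency, rec$gene), , drop = FALSE]
})

setMethod("stableSet", "StabilityResult", function(object, threshold = 0.5) {
  stableSetFromRecords(object@records, threshold)
})

setMethod("stableSet", "data.frame", function(object, threshold = 0.5) {
  stableSetFromRecords(object, threshold)
})

#' @describeIn penalty penalty of a ridge model
setMethod("penalty", "RidgeModel", function(object) object@lambda)

#' @describeIn penalty penalty of a LASSO fit
setMethod("penalty", "LassoFit", function(object) object@lambda)

#' @export
setMethod("coef", "RidgeModel", function(object, ...) {
  stats::setNames(object@weights, object@geneIds)
})

#' @export
setMethod("coef", "LassoFit", function(object, ...) {
  stats::setNames(object@coefficients, object@geneIds)
})

stableSetFromRecords <- function(records, threshold) {
  stopifnot(is.data.frame(records), all(c("gene", "frequency") %in% names(records)))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1) {
    stop("threshold must be a single value in [0, 1]")
  }
  keep <- records[records$frequency > threshold, , drop = FALSE]
  keep <- keep[order(-keep$frequency, keep$gene), , drop = FALSE]
  as.character(keep$gene)
}
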