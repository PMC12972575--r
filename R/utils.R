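#' Derive a per-stage seed from a master seed
#'
#' One master seed deterministically fixes every stochastic stage of a run:
#' the stage name indexes into a fixed stream of seeds drawn under the master
#' seed, so stages can be re-run in isolation with the seed the full run used.
#'
#' @param masterSeed single integer.
#' @param stage stage name (one of the names used by [runDiscovery()]), or an
#'   index into the stream.
#' @return a single integer seed below 2^31.
#' @export
deriveSeed <- function(masterSeed, stage) {
  stages <- c(
    "simulate", "impute", "screen_expression", "screen_methylation",
    "aggregate", "intersect", "cv", "bootstrap", "suite",
    "extra1", "extra2", "extra3"
  )
  idx <- if (is.character(stage)) match(stage, stages) else as.integer(stage)
  if (is.na(idx) || idx < 1L || idx > length(stages)) {
    stop("unknown stage: ", stage)
  }
  old <- .Random.seed.exists()
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(masterSeed))
  seeds <- sample.int(.Machine$integer.max - 1L, length(stages))
  seeds[idx]
}

.Random.seed.exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

assertCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != as.integer(x)) {
    stop(name, " must be a single integer >= ", min)
  }
  as.integer(x)
}

assertScalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(name, " must be a single finite number")
  }
  as.numeric(x)
}

assertMatrixFinite <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x)) stop(name, " must be a numeric matrix")
  if (any(!is.finite(x))) stop(name, " contains non-finite values")
  invisible(x)
}

# Align a named response vector to the columns of a feature matrix; both must
# carry ids and the ids must match as sets.
alignResponse <- function(features, response) {
  if (is.null(colnames(features))) stop("feature matrix must have sample ids")
  if (is.null(names(response))) {
    if (length(response) != ncol(features)) {
      stop("unnamed response must match the number of samples")
    }
    return(stats::setNames(as.numeric(response), colnames(features)))
  }
  missing <- setdiff(colnames(features), names(response))
  if (length(missing)) {
    stop("response missing samples: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  as.numeric(response[colnames(features)])
}
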