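#' @import methods
NULL

#' Simulation configuration for synthetic cohorts
#'
#' Holds the generative knobs for the synthetic training panel and patient
#' cohort: cohort sizes, how many genes carry response weight, how many of
#' those are planted methylation-silenced drivers, the coupling slopes of the
#' planted "hypermethylated -> silenced -> resistant" pattern, and noise
#' levels. Construct with [simConfig()].
#'
#' @slot nGenes number of genes in the universe.
#' @slot nProbesPerGene methylation probes per planted driver gene (non-driver
#'   genes carry a single TSS1500 probe).
#' @slot nTrainCellLines cell lines in the training panel.
#' @slot nPatients patients in the synthetic cohort.
#' @slot nResponseGenes genes with nonzero response weight.
#' @slot nPlantedDrivers planted driver genes (a subset of the response genes).
#' @slot driverMethExprSlope expression change (log2 units) per unit promoter
#'   beta for driver genes; negative under the planted pattern.
#' @slot driverMethIc50Slope direct log2(IC50) change per unit promoter beta
#'   for driver genes; positive under the planted pattern.
#' @slot noiseSdExpr SD of driver-gene expression noise (log2 units).
#' @slot noiseSdResponse SD of response noise (log2 units).
#' @slot seed integer seed fixing all randomness of the generators.
#' @export
setClass("SimConfig",
  representation(
    nGenes = "integer", nProbesPerGene = "integer",
    nTrainCellLines = "integer", nPatients = "integer",
    nResponseGenes = "integer", nPlantedDrivers = "integer",
    driverMethExprSlope = "numeric", driverMethIc50Slope = "numeric",
    noiseSdExpr = "numeric", noiseSdResponse = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  counts <- c(
    nGenes = object@nGenes, nProbesPerGene = object@nProbesPerGene,
    nTrainCellLines = object@nTrainCellLines, nPatients = object@nPatients
  )
  if (any(counts < 1L)) {
    msg <- c(msg, sprintf(
      "counts must be positive (%s)",
      paste(names(counts)[counts < 1L], collapse = ", ")
    ))
  }
  if (object@nResponseGenes < 0L || object@nPlantedDrivers < 0L) {
    msg <- c(msg, "nResponseGenes and nPlantedDrivers must be non-negative")
  }
  if (object@nPlantedDrivers > object@nResponseGenes) {
    msg <- c(msg, "nPlantedDrivers must not exceed nResponseGenes")
  }
  if (object@nResponseGenes > object@nGenes) {
    msg <- c(msg, "nResponseGenes must not exceed nGenes")
  }
  if (object@noiseSdExpr < 0 || object@noiseSdResponse < 0) {
    msg <- c(msg, "noise SDs must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth emitted by the synthetic generators
#'
#' Records what was planted so recovery can be scored: per-gene response
#' weights, driver identities and their probe ids, plus the per-gene baseline
#' expression moments shared by the training panel and the patient cohort.
#'
#' @slot responseWeights named numeric, gene -> response weight w.
#' @slot driverGenes character, planted driver gene ids.
#' @slot driverProbeIds named list, driver gene -> its probe ids (the first is
#'   the signal-carrying TSS1500 probe).
#' @slot geneMeans,geneSds named numeric baseline expression moments.
#' @slot seed integer seed the truth was generated under.
#' @export
setClass("GroundTruth",
  representation(
    responseWeights = "numeric", driverGenes = "character",
    driverProbeIds = "list", geneMeans = "numeric", geneSds = "numeric",
    seed = "integer"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (!all(object@driverGenes %in% names(object@responseWeights))) {
    msg <- c(msg, "every driver gene must carry a response weight")
  } else if (any(object@responseWeights[object@driverGenes] == 0)) {
    msg <- c(msg, "driver response weights must be nonzero")
  }
  if (!all(names(object@responseWeights) %in% names(object@geneMeans))) {
    msg <- c(msg, "responseWeights keys must lie in the gene universe")
  }
  if (length(msg)) msg else TRUE
})

#' Ridge model for log2(IC50) imputation
#'
#' A closed-form L2-penalized linear model trained on a cell-line expression
#' panel, used to impute per-patient log2(IC50) from expression. Columns are
#' standardized internally; centering/scaling constants are stored so
#' prediction reproduces the training transform.
#'
#' @slot geneIds training features, after filtering.
#' @slot weights per-gene coefficients on the standardized scale.
#' @slot intercept mean of the training response.
#' @slot lambda ridge penalty (>= 0).
#' @slot centers,scales per-gene standardization constants.
#' @export
setClass("RidgeModel",
  representation(
    geneIds = "character", weights = "numeric", intercept = "numeric",
    lambda = "numeric", centers = "numeric", scales = "numeric"
  )
)

setValidity("RidgeModel", function(object) {
  msg <- character()
  p <- length(object@geneIds)
  if (length(object@weights) != p || length(object@centers) != p ||
      length(object@scales) != p) {
    msg <- c(msg, "weights/centers/scales must align with geneIds")
  }
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (length(msg)) msg else TRUE
})

#' LASSO fit by cyclic coordinate descent
#'
#' Minimizes (1/2n) * RSS + lambda * sum(|beta_j|) on internally standardized
#' columns. Coefficients are reported on the original scale; the standardized
#' coefficients (on which the penalty acts) are kept alongside so the
#' objective value is verifiable.
#'
#' @slot geneIds feature ids.
#' @slot coefficients per-gene coefficients on the original scale.
#' @slot stdCoefficients coefficients on the standardized scale.
#' @slot intercept intercept on the original scale.
#' @slot lambda L1 penalty.
#' @slot objectiveValue (1/2n) RSS + lambda * sum(|stdCoefficients|).
#' @slot nSweeps coordinate-descent sweeps used.
#' @export
setClass("LassoFit",
  representation(
    geneIds = "character", coefficients = "numeric",
    stdCoefficients = "numeric", intercept = "numeric", lambda = "numeric",
    objectiveValue = "numeric", nSweeps = "integer"
  )
)

setValidity("LassoFit", function(object) {
  msg <- character()
  if (length(object@coefficients) != length(object@geneIds)) {
    msg <- c(msg, "coefficients must align with geneIds")
  }
  if (!is.finite(object@objectiveValue)) msg <- c(msg, "objective must be finite")
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Bootstrap stability-selection result
#'
#' Per-gene selection frequency (selections / B) and mean nonzero coefficient
#' over B bootstrap resamples of the LASSO, the ranking currency of the
#' pipeline.
#'
#' @slot records data.frame with columns gene, frequency, meanNonzeroCoef.
#' @slot B number of bootstrap resamples.
#' @slot lambda penalty (or penalties) used.
#' @slot lambdaPolicy "fixed_full_data" or "retune_each".
#' @slot seed seed the resampling ran under.
#' @export
setClass("StabilityResult",
  representation(
    records = "data.frame", B = "integer", lambda = "numeric",
    lambdaPolicy = "character", seed = "integer"
  )
)

setValidity("StabilityResult", function(object) {
  msg <- character()
  need <- c("gene", "frequency", "meanNonzeroCoef")
  if (!all(need %in% names(object@records))) {
    msg <- c(msg, sprintf("records must have columns %s", paste(need, collapse = ", ")))
  } else if (any(object@records$frequency < 0 | object@records$frequency > 1)) {
    msg <- c(msg, "frequencies must lie in [0, 1]")
  }
  if (object@B < 1L) msg <- c(msg, "B must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Four-parameter logistic dose-response fit
#'
#' viability = bottom + (top - bottom) / (1 + (dose / ic50)^hill), fitted by
#' least squares on log-dose; the IC50 estimate carries the units of the
#' doses.
#'
#' @slot top,bottom asymptotic viabilities (percent).
#' @slot hill hill slope (> 0).
#' @slot ic50 half-maximal inhibitory concentration (> 0).
#' @slot rss residual sum of squares of the fit.
#' @slot converged whether the optimizer reported convergence.
#' @export
setClass("DoseResponseFit",
  representation(
    top = "numeric", bottom = "numeric", hill = "numeric", ic50 = "numeric",
    rss = "numeric", converged = "logical"
  )
)

setValidity("DoseResponseFit", function(object) {
  msg <- character()
  if (object@ic50 <= 0) msg <- c(msg, "ic50 must be positive")
  if (object@top <= object@bottom) msg <- c(msg, "top must exceed bottom")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nGenes, "genes,", object@nPatients, "patients,",
      object@nTrainCellLines, "training cell lines\n")
  cat("  response genes:", object@nResponseGenes,
      "| planted drivers:", object@nPlantedDrivers, "\n")
  cat(sprintf("  driver slopes: expr %.3g / beta, IC50 %.3g / beta\n",
              object@driverMethExprSlope, object@driverMethIc50Slope))
  cat(sprintf("  noise SDs: expr %.3g, response %.3g | seed %d\n",
              object@noiseSdExpr, object@noiseSdResponse, object@seed))
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", length(object@geneMeans), "genes,",
      sum(object@responseWeights != 0), "response genes,",
      length(object@driverGenes), "planted driver(s)\n")
  if (length(object@driverGenes)) {
    cat("  drivers:", paste(object@driverGenes, collapse = ", "), "\n")
  }
})

setMethod("show", "RidgeModel", function(object) {
  cat("RidgeModel:", length(object@geneIds), "genes, lambda =",
      format(object@lambda, digits = 4),
      ", intercept =", format(object@intercept, digits = 4), "\n")
})

setMethod("show", "LassoFit", function(object) {
  cat("LassoFit:", sum(object@coefficients != 0), "of",
      length(object@geneIds), "genes nonzero, lambda =",
      format(object@lambda, digits = 4),
      ", objective =", format(object@objectiveValue, digits = 6), "\n")
})

setMethod("show", "StabilityResult", function(object) {
  cat("StabilityResult: B =", object@B, "resamples,",
      nrow(object@records), "genes, lambda policy =", object@lambdaPolicy, "\n")
  top <- utils::head(object@records[order(-object@records$frequency,
                                          object@records$gene), ], 5L)
  print(top, row.names = FALSE)
})

setMethod("show", "DoseResponseFit", function(object) {
  cat(sprintf(
    "DoseResponseFit: IC50 = %.4g, hill = %.3g, top = %.3g, bottom = %.3g, RSS = %.4g\n",
    object@ic50, object@hill, object@top, object@bottom, object@rss
  ))
})
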