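#' Construct a simulation configuration
#'
#' Defaults describe an EGFR-mutant-cohort-sized study: 2000 genes, 80
#' patients, an 800-cell-line training panel (the scale of a GDSC-class drug
#' screen), 20 genes carrying response weight, and a single planted
#' methylation-silenced driver whose promoter beta depresses its expression
#' (-5 log2 units across the full beta range) and raises log2(IC50) (+2 per
#' unit beta) both through the silenced expression and directly.
#'
#' @param nGenes,nProbesPerGene,nTrainCellLines,nPatients cohort dimensions.
#' @param nResponseGenes genes with nonzero response weight.
#' @param nPlantedDrivers planted drivers (subset of the response genes).
#' @param driverMethExprSlope expression change per unit beta (negative).
#' @param driverMethIc50Slope direct log2(IC50) change per unit beta (positive).
#' @param noiseSdExpr,noiseSdResponse noise SDs (log2 units).
#' @param seed integer seed.
#' @return a validated [SimConfig-class].
#' @export
simConfig <- function(nGenes = 2000L, nProbesPerGene = 3L,
                      nTrainCellLines = 800L, nPatients = 80L,
                      nResponseGenes = 20L, nPlantedDrivers = 1L,
                      driverMethExprSlope = -5, driverMethIc50Slope = 2,
                      noiseSdExpr = 0.4, noiseSdResponse = 0.5, seed = 1L) {
  new("SimConfig",
    nGenes = assertCount(nGenes, "nGenes"),
    nProbesPerGene = assertCount(nProbesPerGene, "nProbesPerGene"),
    nTrainCellLines = assertCount(nTrainCellLines, "nTrainCellLines"),
    nPatients = assertCount(nPatients, "nPatients"),
    nResponseGenes = assertCount(nResponseGenes, "nResponseGenes", min = 0L),
    nPlantedDrivers = assertCount(nPlantedDrivers, "nPlantedDrivers", min = 0L),
    driverMethExprSlope = assertScalar(driverMethExprSlope, "driverMethExprSlope"),
    driverMethIc50Slope = assertScalar(driverMethIc50Slope, "driverMethIc50Slope"),
    noiseSdExpr = assertScalar(noiseSdExpr, "noiseSdExpr"),
    noiseSdResponse = assertScalar(noiseSdResponse, "noiseSdResponse"),
    seed = assertCount(seed, "seed", min = 0L)
  )
}

geneIdsFor <- function(n) sprintf("G%04d", seq_len(n))

#' Generate a synthetic cell-line training panel
#'
#' Emulates a GDSC-style panel: log2 expression drawn i.i.d. normal per gene
#' (gene-specific mean and SD), and measured log2(IC50) that is a linear
#' function of the expression of the response genes plus Gaussian noise,
#' `y = X_sub' w + eps`. Planted driver genes carry negative weights
#' (silenced expression means resistance), the remaining response genes carry
#' random-sign weights.
#'
#' @param config a [SimConfig-class].
#' @return list with `expr` (genes x cell lines, log2), `response` (named
#'   log2(IC50) per cell line), and `truth` (a [GroundTruth-class]).
#' @export
generateTrainingPanel <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  if (config@nTrainCellLines < 3L) {
    stop("nTrainCellLines must be >= 3 to support cross-validation")
  }
  set.seed(config@seed)
  genes <- geneIdsFor(config@nGenes)
  cells <- sprintf("CL%03d", seq_len(config@nTrainCellLines))

  geneMeans <- stats::setNames(stats::runif(config@nGenes, 3, 10), genes)
  geneSds <- stats::setNames(stats::runif(config@nGenes, 0.5, 1.5), genes)

  respGenes <- sort(sample(genes, config@nResponseGenes))
  drivers <- sort(sample(respGenes, config@nPlantedDrivers))
  # response-relevant genes are variable genes; keeps planted signal clear of
  # the low-variance pre-filter
  geneSds[respGenes] <- stats::runif(config@nResponseGenes, 1.0, 1.5)
  w <- stats::setNames(numeric(length(respGenes)), respGenes)
  nonDrv <- setdiff(respGenes, drivers)
  w[nonDrv] <- stats::runif(length(nonDrv), 0.1, 0.3) *
    sample(c(-1, 1), length(nonDrv), replace = TRUE)
  # drivers dominate the response (silenced expression -> resistance),
  # hence negative weights of about 4x the background magnitude
  w[drivers] <- -stats::runif(length(drivers), 1.1, 1.4)

  expr <- matrix(
    stats::rnorm(config@nGenes * config@nTrainCellLines,
                 mean = geneMeans, sd = geneSds),
    nrow = config@nGenes, ncol = config@nTrainCellLines,
    dimnames = list(genes, cells)
  )
  eps <- stats::rnorm(config@nTrainCellLines, 0, config@noiseSdResponse)
  y <- if (length(respGenes)) {
    drop(crossprod(expr[respGenes, , drop = FALSE], w)) + eps
  } else {
    eps
  }
  names(y) <- cells

  probeIds <- driverProbeIdsFor(drivers, config@nProbesPerGene)
  truth <- new("GroundTruth",
    responseWeights = w, driverGenes = drivers, driverProbeIds = probeIds,
    geneMeans = geneMeans, geneSds = geneSds, seed = config@seed
  )
  list(expr = expr, response = y, truth = truth)
}

driverProbeIdsFor <- function(drivers, nProbes) {
  if (!length(drivers)) return(stats::setNames(list(), character()))
  ids <- lapply(seq_along(drivers), function(i) {
    sprintf("cg9%04d%02d", i, seq_len(nProbes))
  })
  stats::setNames(ids, drivers)
}

driverRegions <- function(nProbes) {
  rep(c("TSS1500", "5'UTR", "Body", "TSS200", "1stExon", "3'UTR"),
      length.out = nProbes)
}

#' Generate a synthetic patient cohort with planted drivers
#'
#' Plants the "hypermethylated -> silenced -> resistant" pattern the
#' discovery screen is built to find. For each driver gene, the promoter
#' (TSS1500) probe beta is Uniform(0,1) per patient; a 5'UTR probe is
#' co-methylated with it (SD 0.15) and a Body probe is independent noise.
#' Driver expression is `baseline + driverMethExprSlope * (beta - 0.5) +
#' noise`; the latent true log2(IC50) is `sum(w_g * expr_g) +
#' driverMethIc50Slope * beta_driver + eps`. Non-driver genes carry one
#' TSS1500 probe whose beta is independent of the response. All betas are
#' clipped to \[0.01, 0.99\].
#'
#' @param config a [SimConfig-class].
#' @param truth the [GroundTruth-class] from [generateTrainingPanel()] for the
#'   same gene universe.
#' @param allowSignOverride set TRUE to permit slope signs that violate the
#'   planted pattern (e.g. null cohorts with zero slopes).
#' @return list with `expr` (genes x patients), `meth` (probes x patients
#'   betas), `probeAnnotation` (probe_id, gene, region), and `response`
#'   (latent true log2(IC50) per patient).
#' @export
generatePatientCohort <- function(config, truth, allowSignOverride = FALSE) {
  stopifnot(is(config, "SimConfig"), is(truth, "GroundTruth"))
  if (!setequal(names(truth@geneMeans), geneIdsFor(config@nGenes))) {
    stop("truth was generated for a different gene universe")
  }
  if (config@nPlantedDrivers > 0L && !allowSignOverride &&
      (config@driverMethExprSlope >= 0 || config@driverMethIc50Slope <= 0)) {
    stop("slope signs violate the planted hypermethylated/silenced/resistant ",
         "pattern (need driverMethExprSlope < 0 and driverMethIc50Slope > 0); ",
         "set allowSignOverride = TRUE to force")
  }
  set.seed(as.integer((as.numeric(config@seed) * 69069 + 12345) %% 2^31))
  genes <- geneIdsFor(config@nGenes)
  patients <- sprintf("PT%03d", seq_len(config@nPatients))
  n <- config@nPatients
  drivers <- truth@driverGenes

  # baseline expression, every gene
  expr <- matrix(
    stats::rnorm(config@nGenes * n,
                 mean = truth@geneMeans[genes], sd = truth@geneSds[genes]),
    nrow = config@nGenes, ncol = n, dimnames = list(genes, patients)
  )

  clip <- function(b) pmin(pmax(b, 0.01), 0.99)
  regions <- driverRegions(config@nProbesPerGene)
  annList <- list()
  methRows <- list()
  driverBeta <- matrix(0, nrow = length(drivers), ncol = n,
                       dimnames = list(drivers, patients))

  for (g in drivers) {
    beta <- clip(stats::runif(n))
    driverBeta[g, ] <- beta
    pids <- truth@driverProbeIds[[g]]
    for (k in seq_along(pids)) {
      b <- switch(regions[k],
        "TSS1500" = beta,
        "5'UTR"   = clip(beta + stats::rnorm(n, 0, 0.15)),
        clip(stats::runif(n))
      )
      methRows[[pids[k]]] <- b
    }
    annList[[g]] <- data.frame(
      probe_id = pids, gene = g, region = regions[seq_along(pids)],
      stringsAsFactors = FALSE
    )
    # silencing: expression tracks promoter beta with the planted slope
    expr[g, ] <- truth@geneMeans[g] +
      config@driverMethExprSlope * (beta - 0.5) +
      stats::rnorm(n, 0, config@noiseSdExpr)
  }

  nonDrivers <- setdiff(genes, drivers)
  ndProbes <- sprintf("cg0%06d", seq_along(nonDrivers))
  for (i in seq_along(nonDrivers)) {
    methRows[[ndProbes[i]]] <- clip(stats::runif(n))
  }
  annList[["nonDrivers"]] <- data.frame(
    probe_id = ndProbes, gene = nonDrivers, region = "TSS1500",
    stringsAsFactors = FALSE
  )

  meth <- do.call(rbind, methRows)
  colnames(meth) <- patients
  ann <- do.call(rbind, annList)
  rownames(ann) <- NULL

  w <- truth@responseWeights
  eps <- stats::rnorm(n, 0, config@noiseSdResponse)
  y <- if (length(w)) {
    drop(crossprod(expr[names(w), , drop = FALSE], w)) + eps
  } else {
    eps
  }
  if (length(drivers)) {
    y <- y + config@driverMethIc50Slope * colSums(driverBeta[, , drop = FALSE])
  }
  names(y) <- patients

  list(expr = expr, meth = meth, probeAnnotation = ann, response = y)
}

#' Generate paired MSP Ct values for a known methylation fraction
#'
#' Inverse model of the MSP quantification formula: the Ct difference
#' satisfies `Ct_U - Ct_M = log2(m / (1 - m)) + noise`, so with zero noise the
#' MSP relative-methylation formula applied to any emitted pair returns `m`
#' exactly. Base Cts are drawn Uniform(22, 28) per replicate.
#'
#' @param trueMethFraction m, in the open interval (0, 1).
#' @param noiseSd SD of Ct-difference noise (cycles).
#' @param n number of replicate pairs.
#' @param seed integer seed.
#' @return data.frame with columns `ct_m`, `ct_u`.
#' @export
generateMspCts <- function(trueMethFraction, noiseSd = 0, n = 1L, seed = 1L) {
  m <- assertScalar(trueMethFraction, "trueMethFraction")
  if (m <= 0 || m >= 1) {
    stop("trueMethFraction must lie strictly inside (0, 1): the Ct difference ",
         "log2(m/(1-m)) is undefined at 0 and 1")
  }
  n <- assertCount(n, "n")
  set.seed(as.integer(seed))
  base <- stats::runif(n, 22, 28)
  d <- log2(m / (1 - m)) + stats::rnorm(n, 0, noiseSd)
  data.frame(ct_m = base - d / 2, ct_u = base + d / 2)
}

#' Generate a CCK-8-style viability curve from a known IC50
#'
#' Four-parameter logistic readout:
#' `viability = bottom + (top - bottom) / (1 + (dose/ic50)^hill) + noise`,
#' with top = 100, bottom = 0 by default (percent of untreated control).
#'
#' @param ic50 true IC50 (> 0, same units as doses).
#' @param hill hill slope (> 0).
#' @param doses positive dose vector.
#' @param noiseSd SD of additive viability noise (percent).
#' @param seed integer seed.
#' @param top,bottom asymptotes (percent).
#' @return data.frame with columns `dose`, `viability`.
#' @export
generateViabilityCurve <- function(ic50, hill, doses, noiseSd = 0, seed = 1L,
                                   top = 100, bottom = 0) {
  ic50 <- assertScalar(ic50, "ic50")
  hill <- assertScalar(hill, "hill")
  if (ic50 <= 0) stop("ic50 must be positive")
  if (hill <= 0) stop("hill must be positive")
  if (!is.numeric(doses) || !length(doses) || any(!is.finite(doses)) ||
      any(doses <= 0)) {
    stop("doses must be positive and finite")
  }
  set.seed(as.integer(seed))
  v <- bottom + (top - bottom) / (1 + (doses / ic50)^hill) +
    stats::rnorm(length(doses), 0, noiseSd)
  data.frame(dose = doses, viability = v)
}

#' Write a synthetic cohort to a directory
#'
#' Persists the full acceptance surface as plain text: training expression and
#' response, patient expression, methylation betas, probe annotation, latent
#' response, and the ground truth (JSON).
#'
#' @param panel result of [generateTrainingPanel()].
#' @param cohort result of [generatePatientCohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(panel, cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMatrixTSV(panel$expr, file.path(dir, "train_expression.tsv"), "gene")
  writeResponseTSV(panel$response, file.path(dir, "train_response.tsv"))
  writeMatrixTSV(cohort$expr, file.path(dir, "patient_expression.tsv"), "gene")
  writeMatrixTSV(cohort$meth, file.path(dir, "patient_methylation.tsv"), "probe_id")
  writeProbeAnnotation(cohort$probeAnnotation, file.path(dir, "probe_annotation.tsv"))
  writeResponseTSV(cohort$response, file.path(dir, "latent_response.tsv"))
  writeGroundTruth(panel$truth, file.path(dir, "ground_truth.json"))
  invisible(dir)
}
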