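#' Assemble a discovery-pipeline configuration
#'
#' Inputs may be file paths (the TSV dialects of [readMatrixTSV()],
#' [readResponseTSV()], [readProbeAnnotation()], [readMutationTable()]) or
#' in-memory objects of the same shapes. One master seed deterministically
#' derives every stage seed (see [deriveSeed()]).
#'
#' @param trainExpression genes x cell-lines log2 expression (path or matrix).
#' @param trainResponse measured log2(IC50) per cell line (path or named
#'   vector).
#' @param patientExpression genes x patients log2 expression.
#' @param patientMethylation probes x patients beta matrix.
#' @param probeAnnotation probe annotation (probe_id, gene, region).
#' @param mutationTable optional mutation table; when given, patients are
#'   first restricted to `mutantGene` carriers.
#' @param mutantGene gene whose mutation defines the cohort (default EGFR).
#' @param alpha significance level for both screens.
#' @param regions promoter region classes used for probe aggregation.
#' @param varianceQuantile low-variance gene filter quantile.
#' @param ridgeGrid,ridgeFolds ridge penalty tuning.
#' @param lassoFolds LASSO cross-validation folds.
#' @param B bootstrap resamples.
#' @param threshold stable-set selection-frequency cutoff.
#' @param lambdaPolicy bootstrap penalty policy (see
#'   [bootstrapFrequencies()]).
#' @param masterSeed integer master seed.
#' @param outputDir optional directory for intermediates and the JSON report.
#' @return a validated config (classed list "PipelineConfig").
#' @export
pipelineConfig <- function(trainExpression, trainResponse, patientExpression,
                           patientMethylation, probeAnnotation,
                           mutationTable = NULL, mutantGene = "EGFR",
                           alpha = 0.05, regions = promoterRegions(),
                           varianceQuantile = 0.2,
                           ridgeGrid = 10^seq(-3, 3, length.out = 21),
                           ridgeFolds = 10L, lassoFolds = 10L, B = 500L,
                           threshold = 0.5,
                           lambdaPolicy = "fixed_full_data",
                           masterSeed = 1L, outputDir = NULL) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  cfg <- list(
    trainExpression = trainExpression, trainResponse = trainResponse,
    patientExpression = patientExpression,
    patientMethylation = patientMethylation,
    probeAnnotation = probeAnnotation, mutationTable = mutationTable,
    mutantGene = mutantGene, alpha = alpha, regions = regions,
    varianceQuantile = varianceQuantile, ridgeGrid = ridgeGrid,
    ridgeFolds = assertCount(ridgeFolds, "ridgeFolds", 2L),
    lassoFolds = assertCount(lassoFolds, "lassoFolds", 2L),
    B = assertCount(B, "B"), threshold = threshold,
    lambdaPolicy = match.arg(lambdaPolicy, c("fixed_full_data", "retune_each")),
    masterSeed = assertCount(masterSeed, "masterSeed", 0L),
    outputDir = outputDir
  )
  for (nm in c("trainExpression", "trainResponse", "patientExpression",
               "patientMethylation", "probeAnnotation")) {
    x <- cfg[[nm]]
    if (is.character(x) && !file.exists(x)) stop(nm, " path does not exist: ", x)
  }
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipelineConfig()] (snake_case accepted).
#'
#' @param path YAML file.
#' @param outputDir optional override of the config's output directory.
#' @export
readPipelineConfig <- function(path, outputDir = NULL) {
  raw <- yaml::read_yaml(path)
  names(raw) <- gsub("_(\\w)", "\\U\\1", names(raw), perl = TRUE)
  names(raw)[names(raw) == "b"] <- "B"
  if (!is.null(outputDir)) raw$outputDir <- outputDir
  do.call(pipelineConfig, raw)
}

resolveInput <- function(x, reader) if (is.character(x)) reader(x) else x

#' Run the end-to-end discovery pipeline
#'
#' Executes cohort selection, low-variance filtering, train/patient
#' homogenization, ridge imputation of log2(IC50), Spearman + moderated
#' screens of expression (negative direction) and promoter-aggregated
#' methylation (positive direction) against the imputed response, the
#' sign-constrained intersection, LASSO penalty tuning, bootstrap stability
#' selection, and stable-set extraction. Intermediates and a JSON report are
#' written when the config names an output directory; an empty candidate set
#' completes with a warning and an empty stable set rather than failing.
#'
#' @param config a [pipelineConfig()].
#' @return the run report (named list; see details), invisibly the same as
#'   written to `report.json`.
#' @export
runDiscovery <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  t0 <- proc.time()[["elapsed"]]
  elapsed <- list()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    elapsed[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  stage <- "load_inputs"
  report <- list(package = "methDriveR",
                 version = as.character(utils::packageVersion("methDriveR")),
                 masterSeed = config$masterSeed)
  result <- tryCatch({
    trainExpr <- resolveInput(config$trainExpression, readMatrixTSV)
    trainResp <- resolveInput(config$trainResponse, readResponseTSV)
    patientExpr <- resolveInput(config$patientExpression, readMatrixTSV)
    meth <- resolveInput(config$patientMethylation, readMatrixTSV)
    ann <- resolveInput(config$probeAnnotation, readProbeAnnotation)
    tick("load_inputs")

    stage <- "select_cohort"
    nPatientsIn <- ncol(patientExpr)
    if (!is.null(config$mutationTable)) {
      mut <- resolveInput(config$mutationTable, readMutationTable)
      patientExpr <- selectMutantCohort(mut, patientExpr, config$mutantGene)
    }
    cohortSamples <- colnames(patientExpr)
    tick("select_cohort")

    stage <- "impute"
    trainFiltered <- filterLowVarianceGenes(trainExpr, config$varianceQuantile)
    hom <- homogenizeExpression(trainFiltered, patientExpr)
    Xtr <- t(hom$train)
    ytr <- alignResponse(hom$train, trainResp)
    sel <- selectRidgePenalty(Xtr, ytr, grid = config$ridgeGrid,
                              folds = config$ridgeFolds,
                              seed = deriveSeed(config$masterSeed, "impute"))
    ridge <- fitRidge(Xtr, ytr, sel$lambda)
    imputed <- predictResponse(ridge, hom$test)
    tick("impute")

    stage <- "screen_expression"
    exprSp <- spearmanScreen(patientExpr, imputed)
    exprMod <- moderatedScreen(patientExpr, imputed)
    exprNegative <- combinedFilter(exprSp, exprMod, config$alpha, "negative")
    exprPositive <- combinedFilter(exprSp, exprMod, config$alpha, "positive")
    tick("screen_expression")

    stage <- "screen_methylation"
    methSamples <- intersect(colnames(meth), cohortSamples)
    if (length(methSamples) < 4L) {
      stop("fewer than 4 cohort samples carry methylation data")
    }
    geneMeth <- suppressMessages(
      aggregateProbes(meth[, methSamples, drop = FALSE], ann,
                      regions = config$regions, strategy = "mean")
    )
    methSp <- spearmanScreen(geneMeth, imputed[methSamples])
    methMod <- moderatedScreen(geneMeth, imputed[methSamples])
    methPositive <- combinedFilter(methSp, methMod, config$alpha, "positive")
    methNegative <- combinedFilter(methSp, methMod, config$alpha, "negative")
    tick("screen_methylation")

    stage <- "intersect"
    candidates <- signConstrainedIntersection(
      exprSp[exprSp$feature_id %in% exprNegative,
             c("feature_id", "rho", "p_value")],
      methSp[methSp$feature_id %in% methPositive,
             c("feature_id", "rho", "p_value")]
    )
    tick("intersect")

    stage <- "stability_selection"
    if (nrow(candidates) == 0L) {
      warning("candidate set empty after the sign-constrained intersection; ",
              "stable set is empty")
      stability <- NULL
      metrics <- list(pearson_r = NA_real_, r_squared = NA_real_)
      stable <- character()
      lambda <- NA_real_
    } else {
      Xc <- t(patientExpr[candidates$gene, , drop = FALSE])
      yc <- imputed[rownames(Xc)]
      stability <- bootstrapFrequencies(
        Xc, yc, B = config$B,
        seed = deriveSeed(config$masterSeed, "bootstrap"),
        lambdaPolicy = config$lambdaPolicy, folds = config$lassoFolds
      )
      lambda <- stability@lambda
      fullFit <- fitLasso(Xc, yc, lambda)
      metrics <- if (sum(fullFit@coefficients != 0) > 0) {
        evaluateModel(lassoPredict(fullFit, Xc), yc)
      } else {
        list(pearson_r = NA_real_, r_squared = NA_real_)
      }
      stable <- stableSet(stability, config$threshold)
    }
    tick("stability_selection")

    counts <- list(
      patients_input = nPatientsIn,
      patients_cohort = length(cohortSamples),
      patients_with_methylation = length(methSamples),
      train_genes_input = nrow(trainExpr),
      train_genes_after_variance_filter = nrow(trainFiltered),
      shared_genes = nrow(hom$train),
      expression_genes_tested = sum(!exprSp$flagged),
      expression_significant_negative = length(exprNegative),
      expression_significant_positive = length(exprPositive),
      methylation_genes_tested = sum(!methSp$flagged),
      methylation_significant_positive = length(methPositive),
      methylation_significant_negative = length(methNegative),
      candidates = nrow(candidates),
      stable_genes = length(stable)
    )
    report <- c(report, list(
      seeds = list(impute = deriveSeed(config$masterSeed, "impute"),
                   bootstrap = deriveSeed(config$masterSeed, "bootstrap")),
      parameters = list(
        alpha = config$alpha, regions = config$regions,
        varianceQuantile = config$varianceQuantile,
        ridgeLambda = sel$lambda, lassoLambda = lambda,
        lambdaPolicy = config$lambdaPolicy, B = config$B,
        threshold = config$threshold
      ),
      counts = counts,
      metrics = metrics,
      candidates = candidates,
      stableGenes = stable,
      stability = if (is.null(stability)) NULL else selectionFrequencies(stability)
    ))
    report$elapsed <- elapsed
    list(report = report, imputed = imputed, stability = stability,
         screens = list(expressionSpearman = exprSp, expressionModerated = exprMod,
                        methylationSpearman = methSp, methylationModerated = methMod))
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })

  if (!is.null(config$outputDir)) {
    writeDiscoveryOutputs(result, config)
  }
  invisible(result$report)
}

writeDiscoveryOutputs <- function(result, config) {
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outputDir, f)
  writeResponseTSV(result$imputed, out("imputed_response.tsv"))
  writeScreen <- function(df, f) {
    utils::write.table(df, out(f), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeScreen(result$screens$expressionSpearman, "expression_spearman.tsv")
  writeScreen(result$screens$expressionModerated, "expression_moderated.tsv")
  writeScreen(result$screens$methylationSpearman, "methylation_spearman.tsv")
  writeScreen(result$screens$methylationModerated, "methylation_moderated.tsv")
  writeScreen(result$report$candidates, "candidates.tsv")
  if (!is.null(result$report$stability)) {
    stab <- result$report$stability
    stab$rank <- seq_len(nrow(stab))
    writeScreen(stab, "stability.tsv")
  }
  jsonlite::write_json(result$report, out("report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", null = "null")
  invisible(config$outputDir)
}

#' Repeat the discovery pipeline on fresh synthetic cohorts
#'
#' For each seed, generates a synthetic training panel and patient cohort,
#' runs [runDiscovery()], and scores planted-driver recovery. Per-replicate
#' failures are recorded in the summary rather than aborting the suite.
#'
#' @param configOverrides named list of [simConfig()] arguments to override.
#' @param nReplicates number of replicates (ignored when `seeds` given).
#' @param seeds integer seeds, one per replicate.
#' @param B bootstrap resamples per replicate.
#' @param threshold stable-set cutoff.
#' @param alpha screen significance level.
#' @param allowSignOverride passed to [generatePatientCohort()] (needed for
#'   null cohorts with zero slopes).
#' @return data.frame, one row per replicate: seed, ok, nCandidates,
#'   driverInStable, driverRank1, driverFrequency, falseStable, stableSize;
#'   with attribute "summary" (recoveryRate, meanDriverFrequency,
#'   nullFalseStableRate).
#' @export
runSimulationSuite <- function(configOverrides = list(), nReplicates = 10L,
                               seeds = NULL, B = 500L, threshold = 0.5,
                               alpha = 0.05, allowSignOverride = FALSE) {
  if (is.null(seeds)) seeds <- seq_len(assertCount(nReplicates, "nReplicates"))
  rows <- lapply(seeds, function(s) {
    res <- tryCatch({
      cfg <- do.call(simConfig, utils::modifyList(configOverrides,
                                                  list(seed = as.integer(s))))
      panel <- generateTrainingPanel(cfg)
      cohort <- generatePatientCohort(cfg, panel$truth,
                                      allowSignOverride = allowSignOverride)
      pcfg <- pipelineConfig(
        trainExpression = panel$expr, trainResponse = panel$response,
        patientExpression = cohort$expr, patientMethylation = cohort$meth,
        probeAnnotation = cohort$probeAnnotation,
        alpha = alpha, B = B, threshold = threshold, masterSeed = as.integer(s)
      )
      rep <- suppressWarnings(runDiscovery(pcfg))
      drivers <- panel$truth@driverGenes
      stab <- rep$stability
      freq <- if (!is.null(stab)) {
        stats::setNames(stab$frequency, stab$gene)
      } else {
        numeric()
      }
      driverFreq <- if (length(drivers)) {
        mean(ifelse(drivers %in% names(freq), freq[drivers], 0))
      } else {
        NA_real_
      }
      # rank-1 by frequency: the driver attains the maximum frequency
      # (ties at the top count as rank 1)
      topGenes <- if (!is.null(stab) && nrow(stab)) {
        stab$gene[stab$frequency == max(stab$frequency)]
      } else {
        character()
      }
      data.frame(
        seed = s, ok = TRUE, nCandidates = rep$counts$candidates,
        driverInStable = length(drivers) > 0 &&
          all(drivers %in% rep$stableGenes),
        driverRank1 = length(drivers) > 0 && all(drivers %in% topGenes),
        driverFrequency = driverFreq,
        falseStable = length(setdiff(rep$stableGenes, drivers)),
        stableSize = length(rep$stableGenes),
        stringsAsFactors = FALSE
      )
    }, error = function(e) {
      data.frame(seed = s, ok = FALSE, nCandidates = NA_integer_,
                 driverInStable = NA, driverRank1 = NA,
                 driverFrequency = NA_real_, falseStable = NA_integer_,
                 stableSize = NA_integer_, stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  ok <- out[out$ok, , drop = FALSE]
  attr(out, "summary") <- list(
    recoveryRate = if (nrow(ok)) mean(ok$driverInStable) else NA_real_,
    rank1Rate = if (nrow(ok)) mean(ok$driverRank1) else NA_real_,
    meanDriverFrequency = if (nrow(ok)) mean(ok$driverFrequency) else NA_real_,
    nullFalseStableRate = if (nrow(ok)) mean(ok$falseStable > 0) else NA_real_,
    failures = sum(!out$ok)
  )
  out
}
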