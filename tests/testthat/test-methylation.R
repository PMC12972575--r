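toyMeth <- function() {
  meth <- rbind(
    cg01 = c(0.2, 0.4, 0.6, 0.8),
    cg02 = c(0.4, 0.6, 0.8, 1.0) - 0.2,
    cg03 = c(0.9, 0.1, 0.5, 0.3)
  )
  colnames(meth) <- sprintf("s%d", 1:4)
  ann <- data.frame(
    probe_id = c("cg01", "cg02", "cg03"),
    gene = c("A", "A", "B"),
    region = c("TSS1500", "5'UTR", "Body")
  )
  list(meth = meth, ann = ann)
}

test_that("probe aggregation averages promoter probes and drops probe-free genes", {
  fx <- toyMeth()
  expect_message(
    agg <- aggregateProbes(fx$meth, fx$ann, regions = promoterRegions()),
    "1 gene"
  )
  expect_identical(rownames(agg), "A")
  expect_equal(unname(agg["A", ]), unname((fx$meth["cg01", ] + fx$meth["cg02", ]) / 2))
  # single qualifying probe: row passes through relabeled
  agg2 <- aggregateProbes(fx$meth, fx$ann, regions = "Body")
  expect_equal(unname(agg2["B", ]), unname(fx$meth["cg03", ]))
  # probe order invariance under the mean strategy
  agg3 <- aggregateProbes(fx$meth[c(3, 2, 1), ], fx$ann, regions = promoterRegions())
  expect_equal(agg3["A", ], agg["A", ])
  expect_error(aggregateProbes(fx$meth, fx$ann, regions = "Promoter"), "region token")
  unknown <- fx$meth
  rownames(unknown)[3] <- "cg99"
  expect_error(aggregateProbes(unknown, fx$ann), "missing from the annotation")
})

test_that("max-abs-corr strategy picks the signal-carrying TSS1500 probe", {
  hits <- 0L
  for (s in 1:10) {
    cfg <- smallConfig(seed = s)
    panel <- generateTrainingPanel(cfg)
    cohort <- generatePatientCohort(cfg, panel$truth)
    drv <- panel$truth@driverGenes
    pids <- panel$truth@driverProbeIds[[drv]]
    sub <- cohort$meth[pids, , drop = FALSE]
    ann <- cohort$probeAnnotation
    agg <- aggregateProbes(sub, ann[ann$gene == drv, ],
                           strategy = "max_abs_corr",
                           response = cohort$response)
    # the selected probe is the one whose betas equal the aggregate
    chosen <- pids[apply(sub, 1L, function(b) all(b == agg[drv, ]))]
    tss <- ann$probe_id[ann$gene == drv & ann$region == "TSS1500"]
    hits <- hits + as.integer(identical(chosen, tss))
  }
  expect_gte(hits, 9L)
})

test_that("sign-constrained intersection is exact set logic with stable order", {
  e <- data.frame(feature_id = c("A", "B"), rho = c(-0.5, -0.4),
                  p_value = c(0.01, 0.02))
  m <- data.frame(feature_id = c("B", "C"), rho = c(0.6, 0.7),
                  p_value = c(0.03, 0.001))
  out <- signConstrainedIntersection(e, m)
  expect_identical(out$gene, "B")
  expect_equal(out$expr_rho, -0.4)
  expect_equal(out$meth_p, 0.03)
  # disjoint sets give an empty, well-formed frame
  empty <- signConstrainedIntersection(
    e, data.frame(feature_id = "Z", rho = 0.1, p_value = 0.5))
  expect_identical(nrow(empty), 0L)
  # ordering: meth_p ascending, then gene id
  e2 <- data.frame(feature_id = c("A", "B", "C"), rho = -c(0.5, 0.4, 0.3),
                   p_value = c(0.01, 0.02, 0.03))
  m2 <- data.frame(feature_id = c("A", "B", "C"), rho = c(0.5, 0.4, 0.3),
                   p_value = c(0.02, 0.01, 0.01))
  expect_identical(signConstrainedIntersection(e2, m2)$gene, c("B", "C", "A"))
})

test_that("planted drivers reach the candidate list across seeds", {
  hits <- 0L
  for (s in 1:10) {
    cfg <- smallConfig(seed = s)
    panel <- generateTrainingPanel(cfg)
    cohort <- generatePatientCohort(cfg, panel$truth)
    drv <- panel$truth@driverGenes
    # screen against the latent response (imputation tested elsewhere)
    y <- cohort$response
    spE <- spearmanScreen(cohort$expr, y)
    modE <- moderatedScreen(cohort$expr, y)
    geneMeth <- suppressMessages(aggregateProbes(cohort$meth, cohort$probeAnnotation))
    spM <- spearmanScreen(geneMeth, y)
    modM <- moderatedScreen(geneMeth, y)
    cand <- signConstrainedIntersection(
      spE[spE$feature_id %in% combinedFilter(spE, modE, 0.05, "negative"),
          c("feature_id", "rho", "p_value")],
      spM[spM$feature_id %in% combinedFilter(spM, modM, 0.05, "positive"),
          c("feature_id", "rho", "p_value")]
    )
    hits <- hits + as.integer(drv %in% cand$gene)
  }
  expect_gte(hits, 9L)
})

test_that("joint-null candidate counts match the two-screen chance rate", {
  # with no planted drivers the two omics are independent, so a gene is a
  # candidate with probability ~ (alpha/2)^2: each screen passes at alpha
  # with the required direction half the time
  alpha <- 0.1
  nGenes <- 1000L
  counts <- vapply(1:20, function(s) {
    set.seed(500 + s)
    cfg <- simConfig(nGenes = nGenes, nTrainCellLines = 3L, nPatients = 60L,
                     nResponseGenes = 0L, nPlantedDrivers = 0L, seed = 500 + s)
    panel <- generateTrainingPanel(cfg)
    cohort <- generatePatientCohort(cfg, panel$truth)
    y <- setNames(rnorm(ncol(cohort$expr)), colnames(cohort$expr))
    spE <- spearmanScreen(cohort$expr, y)
    modE <- moderatedScreen(cohort$expr, y)
    geneMeth <- suppressMessages(aggregateProbes(cohort$meth, cohort$probeAnnotation))
    spM <- spearmanScreen(geneMeth, y)
    modM <- moderatedScreen(geneMeth, y)
    nrow(signConstrainedIntersection(
      spE[spE$feature_id %in% combinedFilter(spE, modE, alpha, "negative"),
          c("feature_id", "rho", "p_value")],
      spM[spM$feature_id %in% combinedFilter(spM, modM, alpha, "positive"),
          c("feature_id", "rho", "p_value")]
    ))
  }, numeric(1))
  expected <- nGenes * (alpha / 2)^2
  expect_gt(mean(counts), expected / 3)
  expect_lt(mean(counts), expected * 3)
})

test_that("probe-expression correlation matches its closed forms and null behaviour", {
  beta <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  res <- probeExpressionCorrelation(beta, -beta)
  expect_equal(res$spearman_r, -1)
  expect_equal(res$pearson_r, -1)
  # constant input flagged undefined
  expect_true(probeExpressionCorrelation(rep(0.5, 5), rnorm(5))$flagged)
  # independent noise stays near zero
  small <- 0L
  for (s in 1:10) {
    set.seed(s)
    r <- probeExpressionCorrelation(runif(500), rnorm(500))
    small <- small + as.integer(abs(r$spearman_r) < 0.15 && abs(r$pearson_r) < 0.15)
  }
  expect_gte(small, 9L)
  # planted silencing is detected
  set.seed(99)
  b <- runif(60)
  e <- 8 - 5 * b + rnorm(60, 0, 0.4)
  res <- probeExpressionCorrelation(b, e)
  expect_lt(res$spearman_r, 0)
  expect_lt(res$pearson_r, 0)
  expect_lt(res$spearman_p, 0.05)
  expect_lt(res$pearson_p, 0.05)
})
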