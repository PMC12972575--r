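test_that("variance filter removes exactly the low-variance tail", {
  set.seed(1)
  X <- namedMatrix(rnorm(100 * 20), 100, 20, c("g", "s"))
  expect_identical(filterLowVarianceGenes(X, 0), X)
  expect_equal(nrow(filterLowVarianceGenes(X, 0.2)), 80L)
  # a constant gene has minimal variance and is the first to go
  X["g001", ] <- 5
  kept <- filterLowVarianceGenes(X, 0.1)
  expect_false("g001" %in% rownames(kept))
  expect_error(filterLowVarianceGenes(X, 1), "quantile")
})

test_that("quantile homogenization maps shifted columns back onto the reference", {
  set.seed(2)
  vals <- sort(rnorm(50))
  # training columns share one distribution (they are permutations of it)
  train <- namedMatrix(c(vals, sample(vals), sample(vals)), 50, 3, c("g", "cl"))
  test <- train[, 1, drop = FALSE] + 7          # pure monotone shift
  colnames(test) <- "pt1"
  hom <- homogenizeExpression(train, test)
  expect_identical(hom$train, train)
  expect_equal(unname(hom$test[, 1]), unname(train[, 1]), tolerance = 1e-12)
  # idempotence: identical distributions are untouched
  hom2 <- homogenizeExpression(train, train)
  expect_equal(hom2$test, train, tolerance = 1e-12)
})

test_that("disjoint gene universes fail loudly with both sizes named", {
  a <- namedMatrix(rnorm(20), 5, 4, c("a", "s"))
  b <- namedMatrix(rnorm(20), 5, 4, c("b", "s"))
  expect_error(homogenizeExpression(a, b), "5 genes.*5 genes")
})

test_that("ridge limits: infinite penalty kills weights, zero penalty is OLS", {
  set.seed(3)
  X <- matrix(rnorm(30 * 5), 30, 5)
  colnames(X) <- sprintf("g%02d", 1:5)
  y <- rnorm(30)
  m <- fitRidge(X, y, 1e12)
  expect_lt(max(abs(m@weights)), 1e-6)
  expect_equal(m@intercept, mean(y))

  m0 <- fitRidge(X, y, 0)
  ols <- lm(y ~ scale(X))
  expect_equal(unname(m0@weights), unname(coef(ols)[-1]), tolerance = 1e-8)
})

test_that("closed-form ridge equals the brute-force objective minimizer", {
  set.seed(4)
  for (lam in c(0.5, 5)) {
    X <- matrix(rnorm(50 * 20), 50, 20)
    colnames(X) <- sprintf("g%02d", 1:20)
    y <- rnorm(50)
    m <- fitRidge(X, y, lam)
    expect_lt(max(abs(m@weights - bruteForceRidge(X, y, lam))), 1e-8)
  }
})

test_that("rank-deficient design with zero penalty is refused with advice", {
  X <- matrix(rnorm(10 * 20), 10, 20)
  colnames(X) <- sprintf("g%02d", 1:20)
  expect_error(fitRidge(X, rnorm(10), 0), "penalty > 0")
})

test_that("penalty weight shrinks monotonically in lambda (1-feature closed form)", {
  set.seed(5)
  x <- matrix(rnorm(40), 40, 1, dimnames = list(NULL, "g1"))
  y <- 2 * x[, 1] + rnorm(40, 0, 0.1)
  lams <- c(0, 0.5, 5, 50, 500)
  ws <- vapply(lams, function(l) abs(fitRidge(x, y, l)@weights), numeric(1))
  expect_true(all(diff(ws) <= 1e-12))
  # and matches x'y/(x'x + lambda) on the standardized column
  z <- as.numeric(scale(x)); yc <- y - mean(y)
  expect_equal(unname(fitRidge(x, y, 5)@weights),
               sum(z * yc) / (sum(z^2) + 5), tolerance = 1e-10)
})

test_that("cross-validated penalty selection is deterministic and optimal on its grid", {
  set.seed(6)
  X <- matrix(rnorm(60 * 10), 60, 10)
  colnames(X) <- sprintf("g%02d", 1:10)
  y <- X[, 1] - 0.5 * X[, 2] + rnorm(60, 0, 0.3)
  expect_equal(selectRidgePenalty(X, y, grid = 3.7, folds = 5)$lambda, 3.7)
  s1 <- selectRidgePenalty(X, y, folds = 5, seed = 9)
  s2 <- selectRidgePenalty(X, y, folds = 5, seed = 9)
  expect_identical(s1, s2)
  expect_equal(min(s1$cvTable$cvError),
               s1$cvTable$cvError[s1$cvTable$lambda == s1$lambda])
  expect_error(selectRidgePenalty(X, y, folds = 61), "folds")
})

test_that("prediction honours intercept-only models and sample order", {
  set.seed(7)
  X <- matrix(rnorm(30 * 6), 30, 6)
  colnames(X) <- sprintf("g%02d", 1:6)
  y <- rnorm(30)
  m <- fitRidge(X, y, 1e12)  # effectively intercept-only
  pts <- namedMatrix(rnorm(6 * 4), 6, 4, c("g", "pt"))
  rownames(pts) <- colnames(X)
  pred <- predictResponse(m, pts)
  expect_equal(unname(pred), rep(mean(y), 4), tolerance = 1e-5)
  # column permutation permutes predictions identically
  m2 <- fitRidge(X, y, 2)
  p1 <- predictResponse(m2, pts)
  perm <- c(3, 1, 4, 2)
  expect_equal(predictResponse(m2, pts[, perm]), p1[perm])
  expect_error(predictResponse(m2, pts[-1, , drop = FALSE]), "missing model genes")
})

test_that("held-out cell lines are imputed almost perfectly at zero noise", {
  # well-posed regime (more training lines than genes): at zero response
  # noise the panel law is exactly linear and lightly penalized ridge
  # recovers it
  cfg <- smallConfig(seed = 8, noiseSdResponse = 0, nGenes = 100L,
                     nTrainCellLines = 250L)
  panel <- generateTrainingPanel(cfg)
  trainIdx <- 1:200
  m <- fitRidge(t(panel$expr[, trainIdx]), panel$response[trainIdx], 0.01)
  pred <- predictResponse(m, panel$expr[, -trainIdx])
  expect_gt(cor(pred, panel$response[-trainIdx]), 0.99)
})

test_that("mutant cohort selection filters, de-duplicates, and scales to cohort size", {
  expr <- namedMatrix(rnorm(10 * 5), 10, 5, c("g", "s"))
  mut <- data.frame(
    sample_id = c("s001", "s002", "s002", "s004"),
    gene = c("EGFR", "EGFR", "EGFR", "KRAS"),
    protein_change = c("L858R", "E746_A750del", "T790M", "G12C")
  )
  sel <- selectMutantCohort(mut, expr, "EGFR")
  expect_identical(colnames(sel), c("s001", "s002"))
  expect_error(selectMutantCohort(mut, expr, "TP53"), "no expression samples")

  # a TCGA-LUAD-sized toy: 79 EGFR carriers among 566 patients
  big <- namedMatrix(rnorm(2 * 566), 2, 566, c("g", "s"))
  mutBig <- data.frame(
    sample_id = colnames(big)[1:79], gene = "EGFR", protein_change = "L858R"
  )
  expect_equal(ncol(selectMutantCohort(mutBig, big, "EGFR")), 79L)
})

test_that("ridge models survive JSON serialization", {
  set.seed(9)
  X <- matrix(rnorm(20 * 4), 20, 4)
  colnames(X) <- sprintf("g%02d", 1:4)
  y <- rnorm(20)
  m <- fitRidge(X, y, 2)
  path <- withr::local_tempfile(fileext = ".json")
  writeRidgeModel(m, path)
  m2 <- readRidgeModel(path)
  pts <- namedMatrix(rnorm(4 * 3), 4, 3, c("g", "pt"))
  rownames(pts) <- colnames(X)
  expect_equal(predictResponse(m, pts), predictResponse(m2, pts),
               tolerance = 1e-12)
})
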