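randomProblem <- function(seed, n = 40, p = 8, sparse = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- sprintf("g%02d", seq_len(p))
  beta <- numeric(p)
  if (sparse > 0) beta[seq_len(sparse)] <- c(2, -1.5, 1)[seq_len(sparse)]
  y <- drop(X %*% beta) + rnorm(n, 0, if (sparse > 0) 0.1 else 1)
  list(X = X, y = y, beta = beta)
}

test_that("penalties at or above lambda_max produce the null model", {
  for (s in 1:5) {
    pr <- randomProblem(s)
    lmax <- lassoLambdaMax(pr$X, pr$y)
    expect_true(all(fitLasso(pr$X, pr$y, lmax)@coefficients == 0))
    expect_true(all(fitLasso(pr$X, pr$y, lmax * 1.5)@coefficients == 0))
    # just below lambda_max something enters
    expect_gt(sum(fitLasso(pr$X, pr$y, lmax * 0.99)@coefficients != 0), 0)
  }
})

test_that("unpenalized coordinate descent matches least squares", {
  pr <- randomProblem(2, n = 40, p = 5)
  fit <- fitLasso(pr$X, pr$y, 0, tol = 1e-10)
  ols <- coef(lm(pr$y ~ pr$X))
  expect_equal(unname(fit@coefficients), unname(ols[-1]), tolerance = 1e-6)
  expect_equal(fit@intercept, unname(ols[1]), tolerance = 1e-6)
})

test_that("the objective is non-increasing and locally minimal at the solution", {
  pr <- randomProblem(3, n = 30, p = 8)
  fit <- fitLasso(pr$X, pr$y, 0.1, debug = TRUE)
  trace <- attr(fit, "objectiveTrace")
  expect_true(all(diff(trace) <= 1e-12))
  # local-optimality oracle: random perturbations never beat the solution
  n <- nrow(pr$X)
  std <- methDriveR:::standardizeColumnsN(pr$X)
  yc <- pr$y - mean(pr$y)
  obj <- function(b) sum((yc - std$Z %*% b)^2) / (2 * n) + 0.1 * sum(abs(b))
  b0 <- fit@stdCoefficients
  set.seed(4)
  perturbed <- replicate(1000, obj(b0 + runif(8, -1e-3, 1e-3)))
  expect_true(all(perturbed >= obj(b0) - 1e-12))
  # stored objective value matches its definition
  expect_equal(fit@objectiveValue, obj(b0), tolerance = 1e-12)
})

test_that("coordinate descent agrees with an independent LASSO solver", {
  skip_if_not_installed("glmnet")
  for (s in 1:3) {
    pr <- randomProblem(s + 10, n = 50, p = 12)
    lam <- 0.08
    fit <- fitLasso(pr$X, pr$y, lam, tol = 1e-10)
    gn <- glmnet::glmnet(pr$X, pr$y, alpha = 1, lambda = lam,
                         standardize = TRUE, thresh = 1e-14)
    expect_equal(unname(fit@coefficients),
                 as.numeric(coef(gn))[-1], tolerance = 1e-6)
  }
})

test_that("sparsity is monotone along the descending penalty path", {
  pr <- randomProblem(5, n = 60, p = 15, sparse = 3)
  lmax <- lassoLambdaMax(pr$X, pr$y)
  grid <- exp(seq(log(lmax), log(lmax / 1000), length.out = 30))
  fits <- methDriveR:::lassoPath(pr$X, pr$y, grid)
  nz <- vapply(fits, function(f) sum(f@coefficients != 0), integer(1))
  expect_true(all(diff(nz) >= 0))
})

test_that("cross-validation is deterministic, respects singleton grids, finds support", {
  pr <- randomProblem(6, n = 100, p = 20, sparse = 3)
  expect_equal(cvSelectLambda(pr$X, pr$y, grid = 0.3, folds = 5)$lambda, 0.3)
  a <- cvSelectLambda(pr$X, pr$y, folds = 5, seed = 7)
  b <- cvSelectLambda(pr$X, pr$y, folds = 5, seed = 7)
  expect_identical(a, b)
  expect_error(cvSelectLambda(pr$X[1:4, ], pr$y[1:4], folds = 10), "folds")
  # support recovery across seeds
  hits <- 0L
  for (s in 1:10) {
    pr <- randomProblem(100 + s, n = 100, p = 20, sparse = 3)
    sel <- cvSelectLambda(pr$X, pr$y, folds = 10, seed = s)
    fit <- fitLasso(pr$X, pr$y, sel$lambda)
    hits <- hits + as.integer(all(which(pr$beta != 0) %in% which(fit@coefficients != 0)))
  }
  expect_gte(hits, 9L)
})

test_that("bootstrap frequencies are proportions with the documented edge cases", {
  pr <- randomProblem(8, n = 50, p = 10, sparse = 3)
  one <- bootstrapFrequencies(pr$X, pr$y, B = 1, seed = 1, folds = 5)
  expect_true(all(one@records$frequency %in% c(0, 1)))
  res <- bootstrapFrequencies(pr$X, pr$y, B = 50, seed = 2, folds = 5)
  expect_true(all(res@records$frequency >= 0 & res@records$frequency <= 1))
  # determinism
  res2 <- bootstrapFrequencies(pr$X, pr$y, B = 50, seed = 2, folds = 5)
  expect_identical(res@records, res2@records)
  # true-support genes dominate
  freq <- setNames(res@records$frequency, res@records$gene)
  expect_true(all(freq[c("g01", "g02", "g03")] > 0.9))
})

test_that("bootstrap frequencies are Monte-Carlo stable across disjoint seeds", {
  # penalty held fixed so the two runs differ only in resampling noise
  pr <- randomProblem(9, n = 60, p = 10, sparse = 3)
  lam <- lassoLambdaMax(pr$X, pr$y) / 10
  fa <- bootstrapFrequencies(pr$X, pr$y, B = 500, seed = 1, grid = lam)@records
  fb <- bootstrapFrequencies(pr$X, pr$y, B = 500, seed = 999, grid = lam)@records
  expect_lt(max(abs(fa$frequency - fb$frequency)), 0.1)
})

test_that("stable set thresholding and ranking follow the frequency order", {
  rec <- data.frame(gene = c("A", "B", "C"), frequency = c(0.79, 0.51, 0.49),
                    meanNonzeroCoef = c(-1, 2, 3))
  expect_identical(stableSet(rec, 0.5), c("A", "B"))
  expect_identical(stableSet(rec, 1), character(0))
  sr <- new("StabilityResult", records = rec, B = 100L, lambda = 0.1,
            lambdaPolicy = "fixed_full_data", seed = 1L)
  expect_identical(stableSet(sr), c("A", "B"))
  expect_identical(selectionFrequencies(sr)$gene, c("A", "B", "C"))
})

test_that("fit metrics are the squared-correlation pair", {
  x <- c(1, 2, 3, 5, 8)
  m <- evaluateModel(x, x)
  expect_equal(m$pearson_r, 1)
  expect_equal(m$r_squared, 1)
  m2 <- evaluateModel(x, -x)
  expect_equal(m2$pearson_r, -1)
  expect_equal(m2$r_squared, 1)
  expect_error(evaluateModel(rep(1, 5), x), "zero-variance")
  expect_error(evaluateModel(x[1:2], x[1:2]), "at least 3")
})
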