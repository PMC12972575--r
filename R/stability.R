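#' Smallest L1 penalty with an all-zero solution
#'
#' `lambda_max = max_j |z_j' yc| / n` on standardized columns and centered
#' response: at or above it the LASSO solution is entirely zero.
#'
#' @param X samples x genes matrix.
#' @param y response vector.
#' @return a single penalty value.
#' @export
lassoLambdaMax <- function(X, y) {
  assertMatrixFinite(X, "X")
  y <- as.numeric(y)
  std <- standardizeColumnsN(X)
  yc <- y - mean(y)
  # same summation order as the coordinate-descent inner products, so the
  # all-zero property at lambda_max holds exactly in floating point
  max(abs(vapply(seq_len(ncol(X)), function(j) sum(std$Z[, j] * yc),
                 numeric(1)))) / nrow(X)
}

# standardization with population (1/n) variance so z_j'z_j = n,
# the scaling under which the coordinate-descent updates are unit-step
standardizeColumnsN <- function(X) {
  centers <- colMeans(X)
  n <- nrow(X)
  sds <- sqrt(colMeans((X - rep(centers, each = n))^2))
  scales <- ifelse(sds > 0, sds, 1)
  Z <- sweep(sweep(X, 2L, centers, "-"), 2L, scales, "/")
  list(Z = Z, centers = centers, scales = scales)
}

softThreshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

#' Fit the LASSO by cyclic coordinate descent
#'
#' Minimizes `(1/2n) ||y - b - X beta||^2 + lambda sum(|beta_j|)` on
#' internally standardized columns by cyclic coordinate descent with
#' soft-thresholding; converged when the largest coefficient change in a
#' sweep falls below `tol` (default 1e-7) or after `maxSweeps` (default 1e4)
#' sweeps. Coefficients are reported on the original scale alongside the
#' standardized ones the penalty acts on.
#'
#' @param X samples x genes matrix with column names.
#' @param y response vector.
#' @param penalty L1 penalty lambda >= 0.
#' @param tol convergence tolerance on the max coefficient change.
#' @param maxSweeps sweep cap.
#' @param debug when TRUE, assert the objective is non-increasing after every
#'   sweep and attach the objective trace as attribute "objectiveTrace".
#' @return a [LassoFit-class].
#' @export
fitLasso <- function(X, y, penalty, tol = 1e-7, maxSweeps = 10000L,
                     debug = FALSE) {
  assertMatrixFinite(X, "X")
  y <- as.numeric(y)
  if (any(!is.finite(y))) stop("y contains non-finite values")
  if (length(y) != nrow(X)) stop("y must have one value per row of X")
  lambda <- assertScalar(penalty, "penalty")
  if (lambda < 0) stop("penalty must be >= 0")
  if (is.null(colnames(X))) colnames(X) <- sprintf("g%d", seq_len(ncol(X)))

  n <- nrow(X)
  p <- ncol(X)
  std <- standardizeColumnsN(X)
  Z <- std$Z
  yc <- y - mean(y)
  beta <- numeric(p)
  r <- yc
  objective <- function() sum(r^2) / (2 * n) + lambda * sum(abs(beta))
  trace <- if (debug) objective() else NULL
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    maxDelta <- 0
    for (j in seq_len(p)) {
      old <- beta[j]
      rho <- sum(Z[, j] * r) / n + old
      bj <- softThreshold(rho, lambda)
      if (bj != old) {
        r <- r - Z[, j] * (bj - old)
        beta[j] <- bj
        maxDelta <- max(maxDelta, abs(bj - old))
      }
    }
    if (debug) {
      obj <- objective()
      if (obj > trace[length(trace)] + 1e-12) {
        stop("coordinate-descent objective increased within a sweep")
      }
      trace <- c(trace, obj)
    }
    if (maxDelta < tol || sweeps >= maxSweeps) break
  }
  betaOrig <- beta / std$scales
  fit <- new("LassoFit",
    geneIds = colnames(X), coefficients = betaOrig, stdCoefficients = beta,
    intercept = mean(y) - sum(betaOrig * std$centers), lambda = lambda,
    objectiveValue = objective(), nSweeps = sweeps
  )
  if (debug) attr(fit, "objectiveTrace") <- trace
  fit
}

lassoPredict <- function(fit, X) {
  as.numeric(fit@intercept + X[, fit@geneIds, drop = FALSE] %*% fit@coefficients)
}

#' Select the LASSO penalty by k-fold cross-validation
#'
#' Returns the penalty minimizing mean out-of-fold MSE over a descending
#' log-spaced grid (auto-generated as 100 points from lambda_max down to
#' lambda_max / 1000 when absent), with ties broken toward the larger
#' (sparser) penalty. Fold assignment is a seeded shuffle; fits are
#' warm-started along the path.
#'
#' @param X samples x genes matrix.
#' @param y response vector.
#' @param grid optional penalty grid.
#' @param folds number of folds, default 10.
#' @param seed integer seed for the fold shuffle.
#' @return list with `lambda` and `cvTable` (lambda, cvError, nonzero).
#' @export
cvSelectLambda <- function(X, y, grid = NULL, folds = 10L, seed = 1L) {
  assertMatrixFinite(X, "X")
  y <- as.numeric(y)
  n <- nrow(X)
  folds <- assertCount(folds, "folds", min = 2L)
  if (n < folds) stop("number of samples must be at least the number of folds")
  if (is.null(grid)) {
    lmax <- lassoLambdaMax(X, y)
    if (lmax <= 0) lmax <- 1e-3
    grid <- exp(seq(log(lmax), log(lmax / 1000), length.out = 100L))
  }
  grid <- sort(as.numeric(grid), decreasing = TRUE)
  set.seed(as.integer(seed))
  foldId <- rep(seq_len(folds), length.out = n)[sample.int(n)]
  mse <- matrix(NA_real_, nrow = folds, ncol = length(grid))
  for (f in seq_len(folds)) {
    test <- foldId == f
    fits <- lassoPath(X[!test, , drop = FALSE], y[!test], grid)
    for (k in seq_along(grid)) {
      pred <- lassoPredict(fits[[k]], X[test, , drop = FALSE])
      mse[f, k] <- mean((y[test] - pred)^2)
    }
  }
  cvErr <- colMeans(mse)
  full <- lassoPath(X, y, grid)
  nz <- vapply(full, function(f) sum(f@coefficients != 0), integer(1))
  list(
    lambda = grid[which.min(cvErr)],
    cvTable = data.frame(lambda = grid, cvError = cvErr, nonzero = nz)
  )
}

# warm-started coordinate descent along a descending penalty grid
lassoPath <- function(X, y, grid, tol = 1e-7, maxSweeps = 10000L) {
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("g%d", seq_len(p))
  std <- standardizeColumnsN(X)
  Z <- std$Z
  yc <- y - mean(y)
  beta <- numeric(p)
  r <- yc
  out <- vector("list", length(grid))
  for (k in seq_along(grid)) {
    lambda <- grid[k]
    sweeps <- 0L
    repeat {
      sweeps <- sweeps + 1L
      maxDelta <- 0
      for (j in seq_len(p)) {
        old <- beta[j]
        rho <- sum(Z[, j] * r) / n + old
        bj <- softThreshold(rho, lambda)
        if (bj != old) {
          r <- r - Z[, j] * (bj - old)
          beta[j] <- bj
          maxDelta <- max(maxDelta, abs(bj - old))
        }
      }
      if (maxDelta < tol || sweeps >= maxSweeps) break
    }
    betaOrig <- beta / std$scales
    out[[k]] <- new("LassoFit",
      geneIds = colnames(X), coefficients = betaOrig, stdCoefficients = beta,
      intercept = mean(y) - sum(betaOrig * std$centers), lambda = lambda,
      objectiveValue = sum(r^2) / (2 * n) + lambda * sum(abs(beta)),
      nSweeps = sweeps
    )
  }
  out
}

#' Bootstrap LASSO selection frequencies
#'
#' Resamples patients with replacement B times, fits the LASSO on each
#' resample, and records per gene the selection frequency (resamples with a
#' nonzero coefficient, over B) and the mean coefficient across selecting
#' resamples. Under the default `fixed_full_data` policy the penalty is tuned
#' once by cross-validation on the full data and reused in every resample;
#' `retune_each` re-runs the cross-validation inside every resample.
#' Resamples with fewer than 3 distinct patients are redrawn (counted and
#' reported via a message).
#'
#' @param X samples x genes matrix with gene column names.
#' @param y response vector.
#' @param B number of bootstrap resamples (>= 1).
#' @param seed integer seed fixing resampling (and retuning).
#' @param lambdaPolicy "fixed_full_data" or "retune_each".
#' @param folds cross-validation folds for the penalty tuning.
#' @param grid optional penalty grid passed to [cvSelectLambda()].
#' @return a [StabilityResult-class].
#' @export
bootstrapFrequencies <- function(X, y, B = 500L, seed = 1L,
                                 lambdaPolicy = c("fixed_full_data", "retune_each"),
                                 folds = 10L, grid = NULL) {
  lambdaPolicy <- match.arg(lambdaPolicy)
  assertMatrixFinite(X, "X")
  y <- as.numeric(y)
  B <- assertCount(B, "B")
  n <- nrow(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("g%d", seq_len(ncol(X)))

  lambdaFull <- NA_real_
  if (lambdaPolicy == "fixed_full_data") {
    lambdaFull <- cvSelectLambda(X, y, grid = grid, folds = folds,
                                 seed = seed)$lambda
  }
  set.seed(as.integer(seed))
  counts <- numeric(ncol(X))
  coefSums <- numeric(ncol(X))
  redraws <- 0L
  lambdas <- numeric(B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    while (length(unique(idx)) < 3L) {
      redraws <- redraws + 1L
      idx <- sample.int(n, n, replace = TRUE)
    }
    Xb <- X[idx, , drop = FALSE]
    yb <- y[idx]
    lambda <- if (lambdaPolicy == "fixed_full_data") {
      lambdaFull
    } else {
      cvSelectLambda(Xb, yb, grid = grid, folds = folds,
                     seed = sample.int(.Machine$integer.max - 1L, 1L))$lambda
    }
    fit <- fitLasso(Xb, yb, lambda)
    sel <- fit@coefficients != 0
    counts <- counts + sel
    coefSums <- coefSums + ifelse(sel, fit@coefficients, 0)
    lambdas[b] <- lambda
  }
  if (redraws > 0L) {
    message(redraws, " degenerate resample(s) (< 3 distinct patients) redrawn")
  }
  records <- data.frame(
    gene = colnames(X), frequency = counts / B,
    meanNonzeroCoef = ifelse(counts > 0, coefSums / counts, NA_real_),
    stringsAsFactors = FALSE
  )
  records <- records[order(records$gene), , drop = FALSE]
  rownames(records) <- NULL
  new("StabilityResult",
    records = records, B = B,
    lambda = if (lambdaPolicy == "fixed_full_data") lambdaFull else stats::median(lambdas),
    lambdaPolicy = lambdaPolicy, seed = as.integer(seed)
  )
}

#' Predicted-vs-actual fit metrics
#'
#' Pearson correlation between predicted and actual log2(IC50) and its
#' square, the coefficient of determination of the univariate
#' predicted-vs-actual relation (so `r_squared == pearson_r^2` holds by
#' definition).
#'
#' @param predicted,actual aligned numeric vectors (matched by names when
#'   both are named), n >= 3.
#' @return list with `pearson_r` and `r_squared`.
#' @export
evaluateModel <- function(predicted, actual) {
  if (!is.null(names(predicted)) && !is.null(names(actual))) {
    if (!setequal(names(predicted), names(actual))) {
      stop("predicted and actual cover different samples")
    }
    actual <- actual[names(predicted)]
  }
  predicted <- as.numeric(predicted)
  actual <- as.numeric(actual)
  if (length(predicted) != length(actual)) stop("vectors must be aligned")
  if (length(predicted) < 3L) stop("need at least 3 samples")
  if (stats::sd(predicted) == 0 || stats::sd(actual) == 0) {
    stop("zero-variance vector: correlation undefined")
  }
  r <- stats::cor(predicted, actual)
  list(pearson_r = r, r_squared = r^2)
}
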