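#' Remove low-variance genes from an expression matrix
#'
#' Drops genes whose variance falls strictly below the given quantile of the
#' per-gene variance distribution; survivor order is preserved. A standard
#' pre-step before training the imputation model: flat genes carry no signal
#' but inflate the penalty path.
#'
#' @param expr genes x samples matrix (log2 scale) with rownames.
#' @param quantile variance quantile in \[0, 1); 0 returns the input unchanged.
#' @return the filtered matrix.
#' @export
filterLowVarianceGenes <- function(expr, quantile = 0.2) {
  assertMatrixFinite(expr, "expr")
  if (ncol(expr) < 2L) stop("need at least 2 samples to compute variances")
  if (!is.numeric(quantile) || length(quantile) != 1L || quantile < 0 ||
      quantile >= 1) {
    stop("quantile must lie in [0, 1)")
  }
  v <- rowVars(expr)
  thr <- stats::quantile(v, probs = quantile, names = FALSE)
  expr[v >= thr, , drop = FALSE]
}

rowVars <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1L)
}

#' Homogenize patient expression to a training reference
#'
#' Restricts both matrices to their shared genes and quantile-normalizes each
#' test (patient) column onto the training reference distribution (the mean
#' of the sorted training columns); training values are returned unchanged.
#' Quantile normalization removes monotone platform shifts between the panel
#' and the cohort, which is all the imputation model needs.
#'
#' @param train,test genes x samples matrices with rownames.
#' @return list with elements `train` and `test`, both restricted to the
#'   shared genes (in training order).
#' @export
homogenizeExpression <- function(train, test) {
  assertMatrixFinite(train, "train")
  assertMatrixFinite(test, "test")
  shared <- intersect(rownames(train), rownames(test))
  if (!length(shared)) {
    stop(sprintf(
      "no shared gene ids between training (%d genes) and test (%d genes)",
      nrow(train), nrow(test)
    ))
  }
  tr <- train[shared, , drop = FALSE]
  te <- test[shared, , drop = FALSE]
  target <- rowMeans(apply(tr, 2L, sort))
  g <- length(target)
  teNorm <- apply(te, 2L, function(v) {
    r <- rank(v, ties.method = "average")
    stats::approx(seq_len(g), target, xout = r, rule = 2)$y
  })
  dimnames(teNorm) <- dimnames(te)
  list(train = tr, test = teNorm)
}

standardizeColumns <- function(X) {
  centers <- colMeans(X)
  n <- nrow(X)
  sds <- sqrt(colSums((X - rep(centers, each = n))^2) / (n - 1L))
  scales <- ifelse(sds > 0, sds, 1)
  Z <- sweep(sweep(X, 2L, centers, "-"), 2L, scales, "/")
  list(Z = Z, centers = centers, scales = scales)
}

#' Fit a ridge model by closed form
#'
#' Minimizes `||y - X beta - b||^2 + lambda * ||beta||^2` on internally
#' standardized columns via the SVD, which is exact for any n, p and any
#' lambda > 0. The intercept is the training-response mean (columns are
#' centered). Coefficients live on the standardized scale; the
#' centering/scaling constants are stored in the model and reapplied at
#' prediction time.
#'
#' @param X samples x genes matrix with column names (gene ids).
#' @param y response, one value per row of X (named or aligned by position).
#' @param penalty ridge penalty lambda >= 0.
#' @return a [RidgeModel-class].
#' @export
fitRidge <- function(X, y, penalty) {
  assertMatrixFinite(X, "X")
  lambda <- assertScalar(penalty, "penalty")
  if (lambda < 0) stop("penalty must be >= 0")
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("y must have one value per row of X")
  if (is.null(colnames(X))) colnames(X) <- sprintf("g%d", seq_len(ncol(X)))
  std <- standardizeColumns(X)
  yc <- y - mean(y)
  sv <- svd(std$Z)
  d <- sv$d
  if (lambda == 0) {
    tol <- max(dim(X)) * .Machine$double.eps * max(d, 0)
    if (ncol(X) > nrow(X) - 1L || any(d <= tol)) {
      stop("X is rank-deficient (after centering); lambda = 0 has no unique ",
           "solution - use a penalty > 0")
    }
  }
  shrink <- d / (d^2 + lambda)
  beta <- sv$v %*% (shrink * crossprod(sv$u, yc))
  new("RidgeModel",
    geneIds = colnames(X), weights = as.numeric(beta),
    intercept = mean(y), lambda = lambda,
    centers = as.numeric(std$centers), scales = as.numeric(std$scales)
  )
}

#' Select the ridge penalty by k-fold cross-validation
#'
#' Returns the grid value minimizing mean out-of-fold squared error, with
#' ties broken toward the smaller penalty. Folds are assigned by a seeded
#' shuffle; standardization is re-estimated inside each training fold.
#'
#' @param X samples x genes matrix.
#' @param y response vector.
#' @param grid candidate penalties; default 21 log-spaced points in
#'   10^\[-3, 3\].
#' @param folds number of folds (>= 2, <= n samples).
#' @param seed integer seed for the fold shuffle.
#' @return list with `lambda` (the selected penalty) and `cvTable`
#'   (data.frame lambda, cvError).
#' @export
selectRidgePenalty <- function(X, y, grid = 10^seq(-3, 3, length.out = 21),
                               folds = 10L, seed = 1L) {
  assertMatrixFinite(X, "X")
  y <- as.numeric(y)
  n <- nrow(X)
  folds <- assertCount(folds, "folds", min = 2L)
  if (folds > n) stop("folds must not exceed the number of samples")
  if (!length(grid)) stop("grid must be nonempty")
  grid <- sort(as.numeric(grid))
  set.seed(as.integer(seed))
  foldId <- rep(seq_len(folds), length.out = n)[sample.int(n)]
  sse <- matrix(0, nrow = folds, ncol = length(grid))
  cnt <- integer(folds)
  for (f in seq_len(folds)) {
    test <- foldId == f
    std <- standardizeColumns(X[!test, , drop = FALSE])
    ytr <- y[!test]
    yc <- ytr - mean(ytr)
    sv <- svd(std$Z)
    uty <- crossprod(sv$u, yc)
    Zte <- sweep(sweep(X[test, , drop = FALSE], 2L, std$centers, "-"),
                 2L, std$scales, "/")
    ZteV <- Zte %*% sv$v
    for (k in seq_along(grid)) {
      pred <- mean(ytr) + ZteV %*% ((sv$d / (sv$d^2 + grid[k])) * uty)
      sse[f, k] <- sum((y[test] - pred)^2)
    }
    cnt[f] <- sum(test)
  }
  cvErr <- colMeans(sse / cnt)
  list(
    lambda = grid[which.min(cvErr)],
    cvTable = data.frame(lambda = grid, cvError = cvErr)
  )
}

#' Impute per-sample log2(IC50) from expression
#'
#' Applies a trained [RidgeModel-class] to a patient expression matrix
#' (post-homogenization): each sample's prediction is the intercept plus the
#' dot product of its standardized expression with the model weights.
#'
#' @param model a [RidgeModel-class].
#' @param patientExpr genes x samples matrix containing all model genes.
#' @return named numeric vector of imputed log2(IC50), in patient column
#'   order.
#' @export
predictResponse <- function(model, patientExpr) {
  stopifnot(is(model, "RidgeModel"))
  assertMatrixFinite(patientExpr, "patientExpr")
  missing <- setdiff(model@geneIds, rownames(patientExpr))
  if (length(missing)) {
    stop("patient matrix is missing model genes: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10))
  }
  Z <- (t(patientExpr[model@geneIds, , drop = FALSE]) -
          rep(model@centers, each = ncol(patientExpr))) /
    rep(model@scales, each = ncol(patientExpr))
  stats::setNames(
    as.numeric(model@intercept + Z %*% model@weights),
    colnames(patientExpr)
  )
}

#' @export
setMethod("predict", "RidgeModel", function(object, newdata, ...) {
  predictResponse(object, newdata)
})

#' Restrict an expression matrix to mutation carriers
#'
#' Keeps the samples carrying at least one mutation record for the given
#' gene (e.g. EGFR), collapsing duplicate records, in the expression
#' matrix's column order.
#'
#' @param mutations data.frame with columns `sample_id`, `gene`,
#'   `protein_change`.
#' @param expr genes x samples matrix.
#' @param gene gene symbol to select carriers of.
#' @return the restricted expression matrix.
#' @export
selectMutantCohort <- function(mutations, expr, gene) {
  need <- c("sample_id", "gene", "protein_change")
  if (!is.data.frame(mutations) || !all(need %in% names(mutations))) {
    stop("mutation table must have columns ", paste(need, collapse = ", "))
  }
  assertMatrixFinite(expr, "expr")
  carriers <- unique(mutations$sample_id[mutations$gene == gene])
  keep <- colnames(expr)[colnames(expr) %in% carriers]
  if (!length(keep)) {
    stop("no expression samples carry a ", gene, " mutation record")
  }
  expr[, keep, drop = FALSE]
}
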