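# Shared fixtures, all built in code at test time.

# small synthetic study: quick enough for unit tests, strong planted signal
smallConfig <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(nGenes = 300L, nTrainCellLines = 150L, nPatients = 60L,
         nResponseGenes = 8L, nPlantedDrivers = 1L, seed = as.integer(seed)),
    list(...)
  )
  do.call(simConfig, args)
}

# feature matrix with named dims
namedMatrix <- function(values, nr, nc, prefix = c("f", "s")) {
  matrix(values, nr, nc,
         dimnames = list(sprintf("%s%03d", prefix[1], seq_len(nr)),
                         sprintf("%s%03d", prefix[2], seq_len(nc))))
}

# two vectors with an exact prescribed Pearson correlation
correlatedPair <- function(r, n = 50L, seed = 1L) {
  set.seed(seed)
  x <- rnorm(n)
  z <- rnorm(n)
  z <- residuals(lm(z ~ x))       # orthogonal to x
  x <- as.numeric(scale(x))
  z <- as.numeric(scale(z))
  list(x = x, y = r * x + sqrt(1 - r^2) * z)
}

# brute-force ridge minimizer (independent of the closed form)
bruteForceRidge <- function(X, y, lambda) {
  Z <- scale(X)
  yc <- y - mean(y)
  f <- function(b) sum((yc - Z %*% b)^2) + lambda * sum(b^2)
  g <- function(b) -2 * crossprod(Z, yc - Z %*% b) + 2 * lambda * b
  optim(rep(0, ncol(X)), f, g, method = "BFGS",
        control = list(maxit = 2000, reltol = 1e-16))$par
}
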