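#' Spearman screen of features against a response
#'
#' Per feature: the Spearman correlation computed as the Pearson correlation
#' of mid-ranks, a p-value from the t approximation with n - 2 degrees of
#' freedom, and a Benjamini-Hochberg q-value over all testable features.
#' Constant features have undefined rank correlation: they are flagged,
#' given NA statistics, and excluded from the BH denominator.
#'
#' @param features features x samples matrix with rownames (feature ids) and
#'   colnames (sample ids).
#' @param response per-sample response (named, or aligned by position).
#' @return data.frame with columns `feature_id`, `rho`, `p_value`, `q_value`,
#'   `n`, `direction` ("positive"/"negative"), `flagged`.
#' @export
spearmanScreen <- function(features, response) {
  assertMatrixFinite(features, "features")
  n <- ncol(features)
  if (n < 4L) stop("need at least 4 samples")
  y <- alignResponse(features, response)

  R <- t(apply(features, 1L, rank, ties.method = "average"))
  ry <- rank(y, ties.method = "average")
  Rc <- R - rowMeans(R)
  ryc <- ry - mean(ry)
  ssF <- rowSums(Rc^2)
  ssY <- sum(ryc^2)
  flagged <- ssF == 0 | ssY == 0
  rho <- rep(NA_real_, nrow(features))
  rho[!flagged] <- (Rc[!flagged, , drop = FALSE] %*% ryc) /
    sqrt(ssF[!flagged] * ssY)
  rho <- pmin(pmax(rho, -1), 1)
  p <- corPvalT(rho, n)
  q <- rep(NA_real_, length(p))
  q[!flagged] <- stats::p.adjust(p[!flagged], method = "BH")
  data.frame(
    feature_id = rownames(features), rho = rho, p_value = p, q_value = q,
    n = n, direction = ifelse(rho >= 0, "positive", "negative"),
    flagged = flagged, stringsAsFactors = FALSE
  )
}

# two-sided p for a correlation via the t approximation with n - 2 df
corPvalT <- function(r, n) {
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  t[abs(r) >= 1] <- Inf * sign(r[abs(r) >= 1])
  2 * stats::pt(-abs(t), df = n - 2)
}

# Newton inversion of the trigamma function (for prior-df moment matching)
trigammaInverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:75) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, deriv = 2L)
      y <- y + dif
      if (-dif / y < 1e-10) break
    }
    y
  }, numeric(1))
}

#' Empirical-Bayes moderated linear screen
#'
#' Per-feature simple linear regression of the feature on the response,
#' with residual variances shrunk toward a common prior by empirical Bayes.
#' The prior degrees of freedom d0 and prior variance s0^2 are estimated by
#' moment-matching the log residual variances (digamma/trigamma moment
#' equations, solved by Newton inversion of the trigamma function). The
#' moderated t is `slope / sqrt(s2_tilde / Sxx)` with posterior variance
#' `s2_tilde = (d0 s0^2 + d s2_g) / (d0 + d)` and p-values from the t
#' distribution on d0 + d degrees of freedom.
#'
#' @param features features x samples matrix.
#' @param response per-sample response.
#' @param priorDf optional forced d0 (0 recovers the classical per-feature t;
#'   Inf shrinks every variance fully to `priorVar`).
#' @param priorVar optional forced s0^2 (otherwise moment-estimated).
#' @return data.frame with columns `feature_id`, `slope`, `s2`, `df`,
#'   `prior_df`, `prior_var`, `posterior_var`, `t`, `p_value`, `flagged`.
#' @export
moderatedScreen <- function(features, response, priorDf = NULL, priorVar = NULL) {
  assertMatrixFinite(features, "features")
  n <- ncol(features)
  if (n < 4L) stop("need at least 4 samples")
  y <- alignResponse(features, response)
  if (length(unique(y)) < 2L) {
    stop("response must take at least 2 distinct values")
  }

  xc <- y - mean(y)
  Sxx <- sum(xc^2)
  Fc <- features - rowMeans(features)
  slope <- as.numeric(Fc %*% xc) / Sxx
  d <- n - 2L
  s2 <- pmax((rowSums(Fc^2) - slope^2 * Sxx) / d, 0)
  flagged <- rowSums(Fc^2) == 0

  usable <- !flagged & s2 > 0
  if (is.null(priorDf) || is.null(priorVar)) {
    if (sum(usable) < 2L) {
      est <- list(d0 = 0, s0sq = stats::median(s2[usable]))
    } else {
      est <- fitVariancePrior(s2[usable], d)
    }
  } else {
    est <- list(d0 = NA_real_, s0sq = NA_real_)
  }
  d0 <- if (!is.null(priorDf)) priorDf else est$d0
  s0sq <- if (!is.null(priorVar)) priorVar else est$s0sq

  if (is.infinite(d0)) {
    s2t <- rep(s0sq, length(s2))
  } else if (d0 == 0) {
    s2t <- s2
  } else {
    s2t <- (d0 * s0sq + d * s2) / (d0 + d)
  }
  tmod <- slope / sqrt(s2t / Sxx)
  dfTotal <- d0 + d
  p <- 2 * stats::pt(-abs(tmod), df = dfTotal)
  p[flagged] <- NA_real_
  tmod[flagged] <- NA_real_
  data.frame(
    feature_id = rownames(features), slope = slope, s2 = s2, df = d,
    prior_df = d0, prior_var = s0sq, posterior_var = s2t,
    t = tmod, p_value = p, flagged = flagged, stringsAsFactors = FALSE
  )
}

# Moment-match d0 and s0^2 from observed residual variances with d df each:
# z = log s2 has Var[z] = trigamma(d/2) + trigamma(d0/2) and
# E[z] = log s0^2 + digamma(d/2) - log(d/2) - digamma(d0/2) + log(d0/2).
fitVariancePrior <- function(s2, d) {
  z <- log(pmax(s2, 1e-300))
  e <- z - digamma(d / 2) + log(d / 2)
  evar <- stats::var(e) * (length(e) - 1) / length(e) - trigamma(d / 2)
  if (!is.finite(evar) || evar <= 0) {
    return(list(d0 = Inf, s0sq = exp(mean(e))))
  }
  d0 <- 2 * trigammaInverse(evar)
  s0sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0sq = s0sq)
}

#' Combined significance/direction filter over both screens
#'
#' Features passing the Spearman screen AND the moderated screen at the same
#' alpha, restricted to the requested correlation direction (the sign of the
#' Spearman rho). Returns a set (no duplicates), sorted by feature id.
#'
#' @param spearman output of [spearmanScreen()].
#' @param moderated output of [moderatedScreen()] over the same features.
#' @param alpha significance level in (0, 1) applied to both raw p-values.
#' @param direction "positive", "negative", or "any".
#' @return character vector of feature ids.
#' @export
combinedFilter <- function(spearman, moderated, alpha = 0.05,
                           direction = c("any", "positive", "negative")) {
  direction <- match.arg(direction)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("alpha must lie in (0, 1]")
  }
  if (!setequal(spearman$feature_id, moderated$feature_id)) {
    stop("the two screens must cover the same features")
  }
  m <- moderated[match(spearman$feature_id, moderated$feature_id), ]
  ok <- !spearman$flagged & !m$flagged
  if (alpha < 1) ok <- ok & spearman$p_value < alpha & m$p_value < alpha
  if (direction != "any") ok <- ok & spearman$direction == direction
  sort(unique(spearman$feature_id[which(ok)]))
}
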