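#' MSP relative methylation rate
#'
#' From paired methylation-specific (Ct_M) and unmethylation-specific (Ct_U)
#' qPCR cycle thresholds: `100 * 2^(-Ct_M) / (2^(-Ct_M) + 2^(-Ct_U))`.
#' Computed as `100 / (1 + 2^(Ct_M - Ct_U))`, which only exponentiates the Ct
#' difference and is therefore safe for any finite pair.
#'
#' @param ctM,ctU finite cycle thresholds (vectors recycle).
#' @return relative methylation in percent, in \[0, 100\].
#' @export
mspMethylationRate <- function(ctM, ctU) {
  if (any(!is.finite(ctM)) || any(!is.finite(ctU))) {
    stop("Ct values must be finite")
  }
  100 / (1 + 2^(ctM - ctU))
}

#' Relative expression by the delta-delta-Ct method
#'
#' `2^-((ct_target - ct_ref) - (ct_target_ctrl - ct_ref_ctrl))`: target Ct
#' normalized to a reference gene (e.g. GAPDH) in both the treated and the
#' control condition. Invariant to adding a constant to all four Cts.
#'
#' @param ctTarget,ctRef treated-condition Cts (target and reference gene).
#' @param ctTargetCtrl,ctRefCtrl control-condition Cts.
#' @return fold change relative to the control condition.
#' @export
relativeExpressionDdct <- function(ctTarget, ctRef, ctTargetCtrl, ctRefCtrl) {
  cts <- c(ctTarget, ctRef, ctTargetCtrl, ctRefCtrl)
  if (any(!is.finite(cts))) stop("Ct values must be finite")
  2^(-((ctTarget - ctRef) - (ctTargetCtrl - ctRefCtrl)))
}

#' CCK-8 viability from optical densities
#'
#' `100 * (OD_treated - OD_blank) / (OD_control - OD_blank)`, the percent
#' viability of a treated well relative to the untreated control after blank
#' subtraction (absorbance at 450 nm).
#'
#' @param odTreated,odBlank,odControl optical densities.
#' @return viability percent.
#' @export
cck8Viability <- function(odTreated, odBlank, odControl) {
  if (any(odControl <= odBlank)) {
    stop("control OD must exceed blank OD")
  }
  100 * (odTreated - odBlank) / (odControl - odBlank)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `v = bottom + (top - bottom) / (1 + (dose/ic50)^hill)`, parameterized on
#' log-dose (log(ic50) is the free location parameter) for conditioning.
#' Initialization: top/bottom from the extreme observed responses, ic50 from
#' the dose nearest 50% response; multi-start over hill in {0.5, 1, 2} with
#' best-RSS selection. Asymptote bounds (defaults top in \[80, 120\], bottom
#' in \[-5, 20\]) stabilize sparse curves.
#'
#' @param doses positive dose vector (>= 5 points spanning the inflection).
#' @param viability observed viability percent, one value per dose.
#' @param topBounds,bottomBounds asymptote box constraints.
#' @return a [DoseResponseFit-class].
#' @export
fitFourParamLogistic <- function(doses, viability,
                                 topBounds = c(80, 120),
                                 bottomBounds = c(-5, 20)) {
  if (length(doses) != length(viability)) stop("doses and viability must align")
  if (length(doses) < 5L) stop("need at least 5 dose points")
  if (any(!is.finite(doses)) || any(doses <= 0)) stop("doses must be positive")
  if (any(!is.finite(viability))) stop("viability must be finite")

  ld <- log(doses)
  df <- data.frame(ld = ld, v = viability)
  top0 <- min(max(max(viability), topBounds[1]), topBounds[2])
  bot0 <- min(max(min(viability), bottomBounds[1]), bottomBounds[2])
  mid <- (top0 + bot0) / 2
  lic0 <- ld[which.min(abs(viability - mid))]

  best <- NULL
  for (h0 in c(0.5, 1, 2)) {
    # second start is nudged off the data: a start that already fits exactly
    # makes the initial Jacobian check degenerate
    starts <- list(
      list(top = top0, bottom = bot0, hill = h0, lic50 = lic0),
      list(top = min(top0 + 1, topBounds[2]),
           bottom = max(bot0 - 1, bottomBounds[1]),
           hill = h0 * 1.1, lic50 = lic0 + 0.1)
    )
    for (st in starts) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          v ~ bottom + (top - bottom) / (1 + exp(hill * (ld - lic50))),
          data = df, start = st,
          lower = c(topBounds[1], bottomBounds[1], 1e-3, min(ld) - 10),
          upper = c(topBounds[2], bottomBounds[2], 50, max(ld) + 10),
          control = minpack.lm::nls.lm.control(maxiter = 1000)
        ),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    stop("4PL fit did not converge from any start (hill in {0.5, 1, 2})")
  }
  cf <- stats::coef(best$fit)
  new("DoseResponseFit",
    top = unname(cf["top"]), bottom = unname(cf["bottom"]),
    hill = unname(cf["hill"]), ic50 = exp(unname(cf["lic50"])),
    rss = best$rss, converged = TRUE
  )
}

#' Two-sample t-test with mean and SD summaries
#'
#' Two-tailed unpaired Student's t-test (pooled variance) by default, Welch
#' optionally. When both groups are constant with equal means the statistic
#' is undefined; by convention t = 0, p = 1 is returned with a message.
#'
#' @param groupA,groupB numeric vectors, each n >= 2.
#' @param equalVar pooled-variance Student test when TRUE (default), Welch
#'   when FALSE.
#' @return list with `t`, `p_value`, `df`, `mean_a`, `sd_a`, `mean_b`,
#'   `sd_b`.
#' @export
twoSampleT <- function(groupA, groupB, equalVar = TRUE) {
  a <- as.numeric(groupA)
  b <- as.numeric(groupB)
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("non-finite values")
  summaries <- list(
    mean_a = mean(a), sd_a = stats::sd(a),
    mean_b = mean(b), sd_b = stats::sd(b)
  )
  pooledVar <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (pooledVar == 0) {
    if (mean(a) == mean(b)) {
      message("both groups constant with equal means; returning t = 0, p = 1")
      return(c(list(t = 0, p_value = 1, df = length(a) + length(b) - 2),
               summaries))
    }
    stop("zero within-group variance with unequal means: t is infinite")
  }
  ht <- stats::t.test(a, b, var.equal = equalVar, paired = FALSE,
                      alternative = "two.sided")
  c(list(t = unname(ht$statistic), p_value = ht$p.value,
         df = unname(ht$parameter)), summaries)
}
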