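methRegions <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body", "3'UTR")

#' Default promoter region classes
#'
#' TSS1500, TSS200, 5'UTR and 1stExon: the promoter-proximal probe classes
#' where hypermethylation silences transcription.
#' @export
promoterRegions <- function() methRegions[1:4]

#' Aggregate probe-level methylation to gene level
#'
#' Combines the beta values of each gene's probes falling in the requested
#' region classes, either by the arithmetic mean across probes or by taking
#' the single probe with the largest absolute correlation to a supplied
#' response (`max_abs_corr`). Genes with no qualifying probe are dropped with
#' a message stating how many.
#'
#' @param meth probes x samples beta matrix with probe ids as rownames.
#' @param ann probe annotation data.frame (`probe_id`, `gene`, `region`).
#' @param regions region classes to retain; default the promoter set.
#' @param strategy "mean" or "max_abs_corr".
#' @param response per-sample response, required for `max_abs_corr`.
#' @return genes x samples matrix of gene-level betas.
#' @export
aggregateProbes <- function(meth, ann, regions = promoterRegions(),
                            strategy = c("mean", "max_abs_corr"),
                            response = NULL) {
  strategy <- match.arg(strategy)
  assertMatrixFinite(meth, "meth")
  if (!length(regions)) stop("regions must be nonempty")
  bad <- setdiff(regions, methRegions)
  if (length(bad)) {
    stop("unknown region token(s): ", paste(bad, collapse = ", "))
  }
  unknown <- setdiff(rownames(meth), ann$probe_id)
  if (length(unknown)) {
    stop("probes missing from the annotation: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (strategy == "max_abs_corr") {
    if (is.null(response)) stop("max_abs_corr requires a response")
    y <- alignResponse(meth, response)
  }
  annAll <- ann[ann$probe_id %in% rownames(meth), , drop = FALSE]
  ann <- annAll[annAll$region %in% regions, , drop = FALSE]
  byGene <- split(ann$probe_id, ann$gene)
  out <- matrix(NA_real_, nrow = length(byGene), ncol = ncol(meth),
                dimnames = list(names(byGene), colnames(meth)))
  for (g in names(byGene)) {
    rows <- meth[byGene[[g]], , drop = FALSE]
    out[g, ] <- if (strategy == "mean" || nrow(rows) == 1L) {
      colMeans(rows)
    } else {
      cors <- abs(apply(rows, 1L, function(b) {
        suppressWarnings(stats::cor(b, y, method = "spearman"))
      }))
      cors[is.na(cors)] <- -Inf
      rows[which.max(cors), ]
    }
  }
  dropped <- length(setdiff(unique(annAll$gene), names(byGene)))
  if (dropped > 0L) {
    message(dropped, " gene(s) had no probe in the requested regions and were dropped")
  }
  out[sort(rownames(out)), , drop = FALSE]
}

#' Sign-constrained intersection of the two omics screens
#'
#' Candidate genes are those that are transcriptionally silenced in resistant
#' patients (expression negatively correlated with IC50) AND promoter
#' hypermethylated in resistant patients (methylation positively correlated
#' with IC50). Takes the two per-gene screen tables, intersects their gene
#' sets, and returns both correlation records per candidate, sorted by
#' methylation p-value ascending then gene id (deterministic downstream
#' design matrix).
#'
#' @param exprNegative data.frame with columns `feature_id`, `rho`, `p_value`
#'   for the expression screen's significant negative genes.
#' @param methPositive same, for the methylation screen's significant
#'   positive genes.
#' @return data.frame with columns `gene`, `expr_rho`, `expr_p`, `meth_rho`,
#'   `meth_p`; empty (zero rows) when the sets are disjoint.
#' @export
signConstrainedIntersection <- function(exprNegative, methPositive) {
  for (nm in c("feature_id", "rho", "p_value")) {
    if (!nm %in% names(exprNegative) || !nm %in% names(methPositive)) {
      stop("both inputs need columns feature_id, rho, p_value")
    }
  }
  genes <- intersect(exprNegative$feature_id, methPositive$feature_id)
  e <- exprNegative[match(genes, exprNegative$feature_id), ]
  m <- methPositive[match(genes, methPositive$feature_id), ]
  out <- data.frame(
    gene = genes, expr_rho = e$rho, expr_p = e$p_value,
    meth_rho = m$rho, meth_p = m$p_value, stringsAsFactors = FALSE
  )
  out <- out[order(out$meth_p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Probe-level methylation vs expression correlation
#'
#' Spearman and Pearson correlation between one probe's betas and one gene's
#' expression across samples, each with a t-approximation p-value. The form
#' used to confirm that a candidate's promoter probe tracks its transcript.
#'
#' @param methProbeRow beta values across samples.
#' @param exprGeneRow expression values across the same samples (same order).
#' @return list with `spearman_r`, `spearman_p`, `pearson_r`, `pearson_p`,
#'   `n`, `flagged` (TRUE when either vector is constant).
#' @export
probeExpressionCorrelation <- function(methProbeRow, exprGeneRow) {
  b <- as.numeric(methProbeRow)
  e <- as.numeric(exprGeneRow)
  if (length(b) != length(e)) stop("vectors must be aligned")
  n <- length(b)
  if (n < 4L) stop("need at least 4 samples")
  if (any(!is.finite(b)) || any(!is.finite(e))) stop("non-finite values")
  if (stats::sd(b) == 0 || stats::sd(e) == 0) {
    return(list(spearman_r = NA_real_, spearman_p = NA_real_,
                pearson_r = NA_real_, pearson_p = NA_real_,
                n = n, flagged = TRUE))
  }
  sr <- stats::cor(rank(b, ties.method = "average"),
                   rank(e, ties.method = "average"))
  pr <- stats::cor(b, e)
  list(
    spearman_r = sr, spearman_p = corPvalT(sr, n),
    pearson_r = pr, pearson_p = corPvalT(pr, n),
    n = n, flagged = FALSE
  )
}
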