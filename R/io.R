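#' Read / write feature-by-sample matrices as TSV
#'
#' The on-disk dialect shared by every matrix the pipeline touches: a header
#' row of sample ids, first column the feature id, tab-separated, plain text.
#'
#' @param path file path.
#' @param idCol name of the feature-id column written to the header.
#' @return `readMatrixTSV` returns a numeric matrix with dimnames;
#'   `writeMatrixTSV` returns `path` invisibly.
#' @export
readMatrixTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' @rdname readMatrixTSV
#' @param mat numeric matrix with row and column names.
#' @export
writeMatrixTSV <- function(mat, path, idCol = "feature_id") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- idCol
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a probe annotation table
#'
#' TSV with columns `probe_id`, `gene`, `region`; region tokens follow the
#' 450K/EPIC convention (TSS1500, TSS200, 5'UTR, 1stExon, Body, 3'UTR).
#'
#' @param path file path.
#' @export
readProbeAnnotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("probe_id", "gene", "region")
  if (!all(need %in% names(ann))) {
    stop("probe annotation must have columns ", paste(need, collapse = ", "))
  }
  ann[, need]
}

#' @rdname readProbeAnnotation
#' @param ann data.frame with columns probe_id, gene, region.
#' @export
writeProbeAnnotation <- function(ann, path) {
  utils::write.table(ann[, c("probe_id", "gene", "region")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a mutation table
#'
#' Minimal MAF-like dialect: TSV with header `sample_id`, `gene`,
#' `protein_change`.
#'
#' @param path file path.
#' @return data.frame with those three columns.
#' @export
readMutationTable <- function(path) {
  mut <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "gene", "protein_change")
  if (!all(need %in% names(mut))) {
    stop("mutation table must have columns ", paste(need, collapse = ", "))
  }
  mut[, need]
}

#' Read / write a per-sample response vector as TSV
#'
#' Two columns: `sample_id`, `log2_ic50`.
#'
#' @param path file path.
#' @export
readResponseTSV <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "log2_ic50")
  if (!all(need %in% names(df))) {
    stop("response table must have columns ", paste(need, collapse = ", "))
  }
  stats::setNames(as.numeric(df$log2_ic50), as.character(df$sample_id))
}

#' @rdname readResponseTSV
#' @param response named numeric vector of log2(IC50) values.
#' @export
writeResponseTSV <- function(response, path) {
  stopifnot(!is.null(names(response)))
  utils::write.table(
    data.frame(sample_id = names(response), log2_ic50 = as.numeric(response)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Serialize / restore ground truth as JSON
#'
#' @param truth a [GroundTruth-class].
#' @param path file path.
#' @export
writeGroundTruth <- function(truth, path) {
  stopifnot(is(truth, "GroundTruth"))
  obj <- list(
    response_weights = as.list(truth@responseWeights),
    driver_genes = truth@driverGenes,
    driver_probe_ids = truth@driverProbeIds,
    gene_means = as.list(truth@geneMeans),
    gene_sds = as.list(truth@geneSds),
    seed = truth@seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("GroundTruth",
    responseWeights = unlist(obj$response_weights),
    driverGenes = as.character(obj$driver_genes),
    driverProbeIds = lapply(obj$driver_probe_ids, as.character),
    geneMeans = unlist(obj$gene_means),
    geneSds = unlist(obj$gene_sds),
    seed = as.integer(obj$seed)
  )
}

#' Serialize / restore a ridge imputation model as JSON
#'
#' @param model a [RidgeModel-class].
#' @param path file path.
#' @export
writeRidgeModel <- function(model, path) {
  stopifnot(is(model, "RidgeModel"))
  obj <- list(
    gene_ids = model@geneIds, weights = model@weights,
    intercept = model@intercept, lambda = model@lambda,
    centers = model@centers, scales = model@scales
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRidgeModel
#' @export
readRidgeModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("RidgeModel",
    geneIds = as.character(obj$gene_ids), weights = as.numeric(obj$weights),
    intercept = as.numeric(obj$intercept), lambda = as.numeric(obj$lambda),
    centers = as.numeric(obj$centers), scales = as.numeric(obj$scales)
  )
}
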