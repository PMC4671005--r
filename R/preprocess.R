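#' Read a tab-delimited expression matrix
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers (possibly duplicated before collapsing).  Values are raw,
#' intra-array normalized intensities.
#'
#' @param path path to the tab-delimited file.
#' @return numeric matrix, genes in rows (rownames), samples in columns
#'   (colnames).
#' @seealso [read_sample_conditions()] for the sidecar condition file.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression table needs a gene column plus >=1 sample")
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(df[[1]])
  mat
}

#' Write an expression matrix in the dialect [read_expression_matrix()] reads
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the two-column sample-to-condition sidecar file
#'
#' @param path tab-delimited file with columns `sample` and `condition`;
#'   conditions must be `tumor` or `normal`.
#' @return named character vector, names = samples, values = conditions.
#' @export
read_sample_conditions <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("condition file needs two columns: sample, condition")
  cond <- as.character(df[[2]])
  bad <- setdiff(unique(cond), c("tumor", "normal"))
  if (length(bad) > 0)
    stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  stats::setNames(cond, as.character(df[[1]]))
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the common distribution of rank means:
#' after normalization the sorted values of each column equal the vector of
#' row means of the column-sorted matrix.  Rank ties are resolved by
#' averaging the tied rank means (delegated to
#' [limma::normalizeQuantiles()] with `ties = TRUE`).
#'
#' @param mat numeric matrix, genes x samples, all values finite.
#' @return matrix of the same dimensions and dimnames.
#' @export
quantile_normalize <- function(mat) {
  mat <- .check_expr_matrix(mat)
  if (nrow(mat) < 2) stop("quantile normalization needs >= 2 genes")
  if (ncol(mat) < 2) {
    warning("single sample: quantile normalization is the identity")
    return(mat)
  }
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Average rows that share a gene identifier
#'
#' Rows mapping to the same gene (e.g. multiple probes per Entrez ID) are
#' collapsed to their arithmetic mean, per sample.  Collapsing is done on the
#' normalized intensity scale, before the log2 transform.
#'
#' @param mat numeric matrix with (possibly duplicated) gene rownames.
#' @return matrix with one row per unique gene id; column labels unchanged.
#'   Row order follows the first occurrence of each gene id.
#' @export
collapse_duplicate_genes <- function(mat) {
  mat <- .check_expr_matrix(mat)
  if (nrow(mat) == 0) stop("empty expression matrix")
  ids <- rownames(mat)
  first <- !duplicated(ids)
  counts <- table(ids)
  out <- rowsum(mat, group = ids, reorder = FALSE)
  out <- out / as.vector(counts[rownames(out)])
  # rowsum(reorder = FALSE) keeps first-occurrence order already
  out[ids[first], , drop = FALSE]
}

#' Log2-transform an expression matrix
#'
#' Non-positive entries are a hard error (intra-array normalized intensities
#' are expected to be positive); an explicit `offset` can be supplied when a
#' dataset genuinely needs one.
#'
#' @param mat numeric matrix of positive intensities.
#' @param offset value added to every entry before taking log2 (default 0).
#' @return elementwise log2(mat + offset).
#' @export
log2_transform <- function(mat, offset = 0) {
  mat <- .check_expr_matrix(mat)
  shifted <- mat + offset
  if (any(shifted <= 0)) {
    idx <- which(shifted <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-positive value at gene '%s', sample '%s'; log2 undefined (use offset)",
      rownames(mat)[idx[1]] %||% idx[1], colnames(mat)[idx[2]] %||% idx[2]))
  }
  log2(shifted)
}

#' Full expression preprocessing pipeline
#'
#' Quantile normalization, then collapsing of duplicate gene rows by
#' averaging, then log2 transform -- in that fixed order.
#'
#' @inheritParams log2_transform
#' @return preprocessed matrix, one row per unique gene, log2 scale.
#' @export
preprocess_expression <- function(mat, offset = 0) {
  log2_transform(collapse_duplicate_genes(quantile_normalize(mat)),
                 offset = offset)
}

.check_expr_matrix <- function(mat) {
  if (is.data.frame(mat)) mat <- as.matrix(mat)
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("expression input must be a numeric matrix")
  if (any(!is.finite(mat))) stop("expression matrix contains non-finite values")
  mat
}

`%||%` <- function(a, b) if (is.null(a)) b else a
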