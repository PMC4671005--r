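#' Per-gene log2 fold change (tumor minus normal)
#'
#' @param mat log2-scale expression matrix, genes x samples.
#' @param condition named character vector over the samples with values
#'   `tumor` / `normal`.
#' @return named numeric vector: mean tumor minus mean normal log2
#'   expression per gene.
#' @export
log2_fold_change <- function(mat, condition) {
  cond <- .check_condition(mat, condition)
  rowMeans(mat[, cond == "tumor", drop = FALSE]) -
    rowMeans(mat[, cond == "normal", drop = FALSE])
}

#' Differential-expression criteria of a community
#'
#' Three summaries of how coherently a gene community responds in tumor
#' versus normal tissue:
#' * **c1** -- absolute mean, over the community's genes, of the per-gene
#'   log2 fold change;
#' * **c2** -- Student's two-sample t-test p-value comparing the community
#'   genes' per-gene mean tumor expression against their per-gene mean
#'   normal expression (genes as units, equal variances; set
#'   `genes_as_units = FALSE` to instead compare per-sample community mean
#'   expression with samples as units);
#' * **c3** -- sample standard deviation (n-1) of the community genes' log2
#'   fold changes.
#'
#' @param community character vector of gene ids, all present in `mat`.
#' @param mat log2-scale expression matrix.
#' @inheritParams log2_fold_change
#' @param genes_as_units see above.
#' @return named numeric vector `c(c1, c2, c3)`.
#' @export
diff_expression_criteria <- function(community, mat, condition,
                                     genes_as_units = TRUE) {
  community <- unique(community)
  missing <- setdiff(community, rownames(mat))
  if (length(missing) > 0)
    stop("community genes absent from the expression matrix: ",
         paste(missing, collapse = ", "))
  if (length(community) < 2)
    stop("differential-expression criteria need >= 2 genes")
  cond <- .check_condition(mat, condition)
  sub <- mat[community, , drop = FALSE]
  lfc <- rowMeans(sub[, cond == "tumor", drop = FALSE]) -
    rowMeans(sub[, cond == "normal", drop = FALSE])
  c1 <- abs(mean(lfc))
  c3 <- stats::sd(lfc)
  if (genes_as_units) {
    tm <- rowMeans(sub[, cond == "tumor", drop = FALSE])
    nm <- rowMeans(sub[, cond == "normal", drop = FALSE])
    c2 <- stats::t.test(tm, nm, var.equal = TRUE)$p.value
  } else {
    tm <- colMeans(sub[, cond == "tumor", drop = FALSE])
    nm <- colMeans(sub[, cond == "normal", drop = FALSE])
    c2 <- stats::t.test(tm, nm, var.equal = TRUE)$p.value
  }
  c(c1 = c1, c2 = c2, c3 = c3)
}

#' Differential-expression criteria for every community of a partition
#'
#' @param partition a `partition` over the genes of `mat`.
#' @inheritParams diff_expression_criteria
#' @param min_size smallest community evaluated (default 2).
#' @return data frame: community, size, c1, c2, c3.
#' @export
partition_diff_expression <- function(partition, mat, condition,
                                      genes_as_units = TRUE, min_size = 2) {
  comms <- partition_to_sets(partition)
  comms <- comms[vapply(comms, length, 0L) >= min_size]
  rows <- lapply(names(comms), function(cid) {
    cr <- diff_expression_criteria(comms[[cid]], mat, condition,
                                   genes_as_units)
    data.frame(community = cid, size = length(comms[[cid]]),
               c1 = cr[["c1"]], c2 = cr[["c2"]], c3 = cr[["c3"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.check_condition <- function(mat, condition) {
  if (is.null(names(condition))) {
    if (length(condition) != ncol(mat))
      stop("condition vector does not match the sample count")
    cond <- as.character(condition)
  } else {
    missing <- setdiff(colnames(mat), names(condition))
    if (length(missing) > 0)
      stop("samples without condition labels: ",
           paste(missing, collapse = ", "))
    cond <- as.character(condition[colnames(mat)])
  }
  bad <- setdiff(unique(cond), c("tumor", "normal"))
  if (length(bad) > 0)
    stop("condition labels must be tumor/normal; found: ",
         paste(bad, collapse = ", "))
  if (!all(c("tumor", "normal") %in% cond))
    stop("both tumor and normal samples are required")
  cond
}
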