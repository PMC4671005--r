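#' Equal-frequency discretization
#'
#' Bins a numeric vector at its empirical quantiles.  Duplicate quantile
#' breaks (heavy ties, or fewer unique values than bins) are collapsed, so a
#' constant vector occupies a single bin.
#'
#' @param x numeric vector.
#' @param bins requested number of bins.
#' @return integer vector of bin indices in `1..B`, `B <= bins`.
#' @keywords internal
discretize_equal_frequency <- function(x, bins) {
  if (bins < 1) stop("bins must be >= 1")
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               names = FALSE, type = 7))
  if (length(br) < 2) return(rep(1L, length(x)))
  cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
}

.mi_from_joint <- function(counts) {
  n <- sum(counts)
  px <- rowSums(counts) / n
  py <- colSums(counts) / n
  pxy <- counts / n
  pos <- pxy > 0
  sum(pxy[pos] * log2(pxy[pos] / outer(px, py)[pos]))
}

#' Mutual information between two numeric vectors, in bits
#'
#' Both vectors are discretized by equal-frequency binning and the plug-in
#' mutual information of the joint bin distribution is returned.  With
#' `bins = ceiling(sqrt(n))` (the default) this is the estimator used for the
#' co-expression layer.  A constant vector occupies one bin and yields MI 0.
#'
#' @param x,y numeric vectors of equal length (>= 8).
#' @param bins number of bins per margin; default `ceiling(sqrt(length(x)))`.
#' @return nonnegative mutual information in bits; symmetric in `(x, y)`.
#' @export
mutual_information <- function(x, y, bins = ceiling(sqrt(length(x)))) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 8) stop("mutual information needs >= 8 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  xb <- discretize_equal_frequency(x, bins)
  yb <- discretize_equal_frequency(y, bins)
  mi <- .mi_from_joint(table(xb, yb))
  max(mi, 0)
}

#' All-pairs mutual information for the rows of a matrix
#'
#' Vectorized equivalent of calling [mutual_information()] on every row pair:
#' each gene is discretized once, then joint bin counts for all pairs are
#' accumulated by indicator-matrix cross products (one BLAS call per bin
#' pair), which keeps the complete co-expression graph tractable for a few
#' thousand genes.
#'
#' @param mat numeric matrix, genes x samples.
#' @inheritParams mutual_information
#' @return symmetric genes x genes matrix of MI values in bits (diagonal =
#'   per-gene entropy).
#' @export
mi_matrix <- function(mat, bins = ceiling(sqrt(ncol(mat)))) {
  if (ncol(mat) < 8) stop("mutual information needs >= 8 samples")
  n <- ncol(mat)
  g <- nrow(mat)
  D <- t(apply(mat, 1, discretize_equal_frequency, bins = bins))
  B <- max(D)
  ind <- lapply(seq_len(B), function(b) t(D == b) * 1)   # n x g per bin
  marg <- vapply(ind, colSums, numeric(g))               # g x B counts
  mi <- matrix(0, g, g)
  for (a in seq_len(B)) {
    for (b in seq_len(B)) {
      C <- crossprod(ind[[a]], ind[[b]])                 # joint counts
      E <- tcrossprod(marg[, a], marg[, b])              # marginal products
      pos <- C > 0
      if (any(pos)) mi[pos] <- mi[pos] + C[pos] * log2(C[pos] * n / E[pos])
    }
  }
  mi <- mi / n
  mi <- (mi + t(mi)) / 2      # exact symmetry against roundoff
  mi[mi < 0] <- 0
  dimnames(mi) <- list(rownames(mat), rownames(mat))
  mi
}
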