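#' Normalized mutual information between two partitions
#'
#' Contingency-table mutual information normalized, by default, by the
#' arithmetic mean of the two partition entropies:
#' \deqn{NMI(A, B) = \frac{I(A; B)}{(H(A) + H(B))/2}.}
#' Equals 1 iff the partitions coincide up to label renaming and 0 when one
#' partition is a single block (no information).  Other normalizers are
#' available via `variant`.
#'
#' @param a,b `partition` objects (or named membership vectors) on the same
#'   node set.
#' @param variant normalizer: `"mean"` (default), `"min"`, `"max"`,
#'   `"sqrt"` or `"joint"`.
#' @return value in `[0, 1]`.
#' @export
nmi <- function(a, b, variant = c("mean", "min", "max", "sqrt", "joint")) {
  variant <- match.arg(variant)
  ab <- .align_partitions(a, b)
  tab <- table(ab$a, ab$b)
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy)
  py <- colSums(pxy)
  pos <- pxy > 0
  I <- sum(pxy[pos] * log(pxy[pos] / outer(px, py)[pos]))
  Hx <- -sum(px[px > 0] * log(px[px > 0]))
  Hy <- -sum(py[py > 0] * log(py[py > 0]))
  if (Hx + Hy == 0) return(1)      # both trivial one-block partitions
  norm <- switch(variant,
                 mean = (Hx + Hy) / 2,
                 min = min(Hx, Hy),
                 max = max(Hx, Hy),
                 sqrt = sqrt(Hx * Hy),
                 joint = -sum(pxy[pos] * log(pxy[pos])))
  if (norm == 0) return(0)
  min(max(I / norm, 0), 1)
}

#' Rand index between two partitions
#'
#' Fraction of node pairs on which the two partitions agree (both together
#' or both apart) -- the pairwise co-assignment overlap used for the
#' alpha-robustness check.
#'
#' @inheritParams nmi
#' @return value in `[0, 1]`; 1 iff the partitions coincide.
#' @export
rand_index <- function(a, b) {
  ab <- .align_partitions(a, b)
  tab <- table(ab$a, ab$b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  (total + 2 * sum_ij - sum_i - sum_j) / total
}

.align_partitions <- function(a, b) {
  if (is.null(names(a)) || is.null(names(b)))
    stop("partitions must be named by node id")
  nodes <- sort(names(a))
  if (!identical(nodes, sort(names(b))))
    stop("partitions are defined on different node sets")
  list(a = unclass(a)[nodes], b = unclass(b)[nodes])
}
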