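#' Disparity-filter p-value of an edge at one endpoint
#'
#' Under the null model, a node of degree k distributes its strength over its
#' edges as k-1 uniform breakpoints; an edge carrying a fraction
#' `p = weight / strength` of the strength then has survival probability
#' `(1 - p)^(k - 1)`.  Small values flag edges carrying a significantly
#' larger share of the node's strength than the uniform null allows.
#' Degree-1 endpoints return 1: a pendant edge can never be significant from
#' its own side.
#'
#' @param weight positive edge weight(s).
#' @param strength positive endpoint strength(s), `weight <= strength`.
#' @param degree endpoint degree(s), integer >= 1.
#' @return p-value(s) in `[0, 1]`; vectorized over its arguments.
#' @export
disparity_pvalue <- function(weight, strength, degree) {
  if (any(weight <= 0) || any(strength <= 0))
    stop("weight and strength must be positive")
  if (any(degree < 1)) stop("degree must be >= 1")
  if (any(weight > strength * (1 + 1e-12)))
    stop("edge weight exceeds endpoint strength")
  (1 - pmin(weight / strength, 1))^(degree - 1)
}

#' Extract the multiscale backbone of a weighted layer
#'
#' Keeps an edge iff its disparity p-value is below `alpha` at at least one
#' endpoint (the original filter's OR convention, which preserves the
#' backbones of hubs at every scale).  The node set is preserved; filtering
#' only removes edges, so backbones are nested in `alpha`.
#'
#' @param layer weighted layer graph (must carry a `weight` edge attribute).
#' @param alpha significance level in (0, 1).
#' @return the filtered layer (same nodes, subset of edges, weights kept).
#' @export
disparity_filter <- function(layer, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("alpha must be a single value in (0, 1)")
  if (is.null(igraph::E(layer)$weight))
    stop("disparity filter requires a weighted layer")
  if (igraph::ecount(layer) == 0) return(layer)
  el <- igraph::as_edgelist(layer, names = FALSE)
  w <- igraph::E(layer)$weight
  s <- igraph::strength(layer)
  k <- igraph::degree(layer)
  p1 <- disparity_pvalue(w, s[el[, 1]], k[el[, 1]])
  p2 <- disparity_pvalue(w, s[el[, 2]], k[el[, 2]])
  keep <- pmin(p1, p2) < alpha
  igraph::delete_edges(layer, igraph::E(layer)[!keep])
}

#' Edge density of a layer
#' @param layer a layer graph.
#' @return fraction of the `choose(n, 2)` possible edges present.
#' @export
layer_density <- function(layer) {
  n <- igraph::vcount(layer)
  if (n < 2) return(0)
  igraph::ecount(layer) / choose(n, 2)
}

#' Global weight-threshold filter (comparison utility)
#'
#' Retains edges with weight >= threshold.  Provided only to contrast with
#' [disparity_filter()]; global thresholding removes whole nodes together
#' with their edges on co-targeting/co-expression topologies and is not the
#' production path.
#'
#' @param layer weighted layer.
#' @param threshold minimum weight retained.
#' @return filtered layer.
#' @export
threshold_filter <- function(layer, threshold) {
  if (is.null(igraph::E(layer)$weight)) stop("requires a weighted layer")
  igraph::delete_edges(layer, igraph::E(layer)[igraph::E(layer)$weight < threshold])
}
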