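#' One-sided Fisher exact test of layer / gold-standard edge overlap
#'
#' Tests enrichment of a validated ("gold standard") interaction set among a
#' layer's edges over the universe of all unordered node pairs of the layer's
#' node set.  Gold edges with an endpoint outside the layer's node set are
#' ignored.
#'
#' @param layer a layer graph.
#' @param gold two-column data frame (or matrix) of gold-standard edges.
#' @param universe_pairs number of node pairs in the universe; default
#'   `choose(vcount(layer), 2)`.
#' @return one-sided (enrichment) Fisher exact p-value.
#' @export
fisher_overlap_test <- function(layer, gold, universe_pairs = NULL) {
  nodes <- igraph::V(layer)$name
  gold_keys <- .pair_keys(as.character(gold[[1]]), as.character(gold[[2]]))
  inside <- gold[[1]] %in% nodes & gold[[2]] %in% nodes
  gold_keys <- unique(gold_keys[inside])
  if (length(gold_keys) == 0)
    stop("gold standard has no edges within the layer's node namespace")
  el <- igraph::as_edgelist(layer, names = TRUE)
  layer_keys <- unique(.pair_keys(el[, 1], el[, 2]))
  if (is.null(universe_pairs)) universe_pairs <- choose(length(nodes), 2)
  a <- sum(layer_keys %in% gold_keys)
  b <- length(layer_keys) - a
  cc <- length(gold_keys) - a
  d <- universe_pairs - a - b - cc
  if (d < 0) stop("universe smaller than the union of layer and gold edges")
  stats::fisher.test(matrix(c(a, b, cc, d), nrow = 2),
                     alternative = "greater")$p.value
}

.pair_keys <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Read a two-column edge list (PPI or gold standard)
#' @param path TSV with two columns of gene ids (header optional but
#'   recommended: `gene1`, `gene2`).
#' @return data frame with columns `gene1`, `gene2`.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("edge list needs two columns")
  stats::setNames(df[, 1:2], c("gene1", "gene2"))
}

#' Evaluate a grid of disparity-filter significance levels
#'
#' For every alpha in the grid the layer is filtered and a report row
#' records the surviving edge count, density and Fisher-exact enrichment of
#' the gold standard.  The recommended alpha is the one of minimal density
#' among those whose Fisher p-value stays below `fisher_sig`; ties break
#' toward the smaller alpha (sparser is safer).  If no alpha qualifies the
#' recommendation is `NA` with a warning.
#'
#' @param layer weighted layer to filter.
#' @param gold gold-standard edge data frame (see [fisher_overlap_test()]).
#' @param alphas significance grid, each value in `[0.01, 0.5]`.
#' @param fisher_sig significance required of the gold-standard overlap
#'   (default 0.05).
#' @return list with `report` (data frame: alpha, edges, density, fisher_p)
#'   and `recommended` (alpha or NA).
#' @export
select_alpha <- function(layer, gold, alphas = c(0.01, 0.05, 0.1, 0.25, 0.5),
                         fisher_sig = 0.05) {
  if (length(alphas) == 0) stop("empty alpha grid")
  if (any(alphas < 0.01 - 1e-9) || any(alphas > 0.5 + 1e-9))
    stop("alpha grid must lie within [0.01, 0.5]")
  alphas <- sort(unique(alphas))
  rows <- lapply(alphas, function(a) {
    f <- disparity_filter(layer, a)
    fp <- if (igraph::ecount(f) == 0) 1 else fisher_overlap_test(f, gold)
    data.frame(alpha = a, edges = igraph::ecount(f),
               density = layer_density(f), fisher_p = fp)
  })
  report <- do.call(rbind, rows)
  ok <- report$fisher_p < fisher_sig & report$edges > 0
  if (!any(ok)) {
    warning("no alpha in the grid satisfies the gold-standard criterion")
    recommended <- NA_real_
  } else {
    cand <- report[ok, ]
    cand <- cand[order(cand$density, cand$alpha), ]
    recommended <- cand$alpha[1]
  }
  list(report = report, recommended = recommended)
}

#' Cross-layer edge-count balance
#'
#' The second alpha-selection criterion: after filtering, no layer should
#' dominate the multi-network.  Balance is the ratio of the largest to the
#' smallest per-layer edge count, compared to a fold-factor.
#'
#' @param edge_counts named vector of per-layer edge counts after filtering.
#' @param fold_factor maximum tolerated max/min ratio (default 10).
#' @return list with `fold` (observed ratio) and `balanced` (logical).
#' @export
balance_check <- function(edge_counts, fold_factor = 10) {
  ec <- edge_counts[edge_counts > 0]
  if (length(ec) == 0) return(list(fold = Inf, balanced = FALSE))
  fold <- max(edge_counts) / min(ec)
  if (any(edge_counts == 0)) fold <- Inf
  list(fold = fold, balanced = is.finite(fold) && fold <= fold_factor)
}

#' Robustness of the community structure to the significance level
#'
#' Re-runs the full downstream detection (per-layer consensus plus
#' cross-layer consensus) at `alpha/2`, `alpha` and `2*alpha` (clipped to
#' `[0.01, 0.5]`) and reports pairwise partition agreement: normalized
#' mutual information and the fraction of gene pairs classified identically
#' (Rand index).  A stable analysis should show near-perfect overlap.
#'
#' @param multinet unfiltered multi-network.
#' @param alpha reference significance level.
#' @param algorithm,n_runs,tau,seed detection configuration, as in
#'   [consensus_partition()].
#' @param filter_layers names of the layers to filter (default: all but
#'   `ppi`).
#' @return list with `alphas`, `partitions`, `nmi` and `rand` pairwise
#'   matrices, and `min_nmi` / `min_rand` summaries.
#' @export
robustness_check <- function(multinet, alpha, algorithm = "louvain",
                             n_runs = 100, tau = 0.5, seed = 1,
                             filter_layers = NULL) {
  alphas <- unique(pmin(pmax(c(alpha / 2, alpha, 2 * alpha), 0.01), 0.5))
  if (length(alphas) == 1) {
    warning("alpha grid collapsed to a single value after clipping")
    part <- detect_multinetwork_communities(
      multinet, alpha = alphas, algorithm = algorithm, n_runs = n_runs,
      tau = tau, seed = seed, filter_layers = filter_layers)$partition
    one <- matrix(1, 1, 1)
    return(list(alphas = alphas, partitions = list(part),
                nmi = one, rand = one, min_nmi = 1, min_rand = 1))
  }
  parts <- lapply(seq_along(alphas), function(i)
    detect_multinetwork_communities(
      multinet, alpha = alphas[i], algorithm = algorithm, n_runs = n_runs,
      tau = tau, seed = seed + i - 1, filter_layers = filter_layers)$partition)
  m <- length(parts)
  nmi_mat <- rand_mat <- diag(1, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      nmi_mat[i, j] <- nmi_mat[j, i] <- nmi(parts[[i]], parts[[j]])
      rand_mat[i, j] <- rand_mat[j, i] <- rand_index(parts[[i]], parts[[j]])
    }
  }
  off <- upper.tri(nmi_mat)
  list(alphas = alphas, partitions = parts, nmi = nmi_mat, rand = rand_mat,
       min_nmi = min(nmi_mat[off]), min_rand = min(rand_mat[off]))
}
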