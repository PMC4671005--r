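#' Deterministically derive per-run seeds from a master seed
#' @param seed master seed (integer or NULL for non-reproducible seeds).
#' @param n number of seeds.
#' @return integer vector of length `n`.
#' @keywords internal
spawn_seeds <- function(seed, n) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Co-assignment consensus matrix of a set of partitions
#'
#' Entry (i, j) is the fraction of partitions placing nodes i and j in the
#' same community.  All partitions must cover the identical node set; rows
#' and columns are ordered by sorted node id.
#'
#' @param partitions list of >= 2 `partition` objects on one node set.
#' @return symmetric numeric matrix with unit diagonal, entries quantized to
#'   multiples of `1/length(partitions)`, dimnames = sorted node ids.
#' @export
consensus_matrix <- function(partitions) {
  if (length(partitions) < 2) stop("need >= 2 partitions")
  nodes <- sort(names(partitions[[1]]))
  for (p in partitions) {
    if (!identical(sort(names(p)), nodes))
      stop("partitions are defined on different node sets")
  }
  D <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (p in partitions) {
    lab <- unclass(p)[nodes]
    D <- D + outer(lab, lab, "==")
  }
  D / length(partitions)
}

.partition_from_binary <- function(D) {
  g <- igraph::graph_from_adjacency_matrix(D >= 0.5, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  as_partition(stats::setNames(comp, rownames(D)))
}

.is_block_diagonal <- function(D, tol = 1e-9) {
  binary <- all(abs(D) < tol | abs(D - 1) < tol)
  if (!binary) return(FALSE)
  m <- unclass(.partition_from_binary(D))[rownames(D)]
  all(abs(D - outer(m, m, "==")) < tol)
}

.graph_from_consensus <- function(D, tau) {
  Dt <- D
  Dt[Dt < tau] <- 0
  diag(Dt) <- 0
  igraph::graph_from_adjacency_matrix(Dt, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Consensus partition of one layer over repeated stochastic runs
#'
#' Iterated consensus clustering: the algorithm is run `n_runs` times with
#' distinct seeds; the co-assignment matrix of the runs is thresholded at
#' `tau` (entries below `tau` are zeroed) and used as a weighted graph for
#' the next round, until all runs agree (the consensus matrix is 0/1 and
#' block diagonal) or `max_iter` rounds have passed.  A deterministic
#' algorithm converges in one round to its single-run partition.
#'
#' @param layer weighted layer graph.
#' @param algorithm registered algorithm name.
#' @param n_runs runs per round (default 100).
#' @param tau consensus threshold in (0, 1), default 0.5 (majority rule).
#' @param max_iter maximum consensus rounds (default 20).
#' @param seed master seed; per-run seeds are spawned from it.
#' @return a `partition`; attribute `converged` records whether full
#'   agreement was reached (otherwise the majority partition is returned
#'   with a warning) and `iterations` the rounds used.
#' @export
consensus_partition <- function(layer, algorithm = "louvain", n_runs = 100,
                                tau = 0.5, max_iter = 20, seed = NULL) {
  if (n_runs < 2) stop("n_runs must be >= 2")
  if (tau <= 0 || tau >= 1) stop("tau must be in (0, 1)")
  seeds <- matrix(spawn_seeds(seed, n_runs * max_iter), nrow = n_runs)
  g <- layer
  D <- NULL
  for (it in seq_len(max_iter)) {
    parts <- lapply(seq_len(n_runs), function(r)
      detect_communities(g, algorithm, seed = seeds[r, it]))
    D <- consensus_matrix(parts)
    if (.is_block_diagonal(D)) {
      out <- .partition_from_binary(D)
      attr(out, "converged") <- TRUE
      attr(out, "iterations") <- it
      return(out)
    }
    g <- .graph_from_consensus(D, tau)
  }
  warning("consensus did not converge in ", max_iter,
          " iterations; returning majority partition")
  out <- .partition_from_binary(D)
  attr(out, "converged") <- FALSE
  attr(out, "iterations") <- max_iter
  out
}

#' Cross-layer consensus partition of the multi-network
#'
#' Combines the best (per-layer consensus) partitions into the multi-network
#' community structure: their co-assignment matrix is thresholded at `tau`
#' and the iterated consensus procedure is applied to the resulting weighted
#' agreement graph.  Layers are weighted equally.
#'
#' @param layer_partitions list of one `partition` per layer (>= 2), shared
#'   node set.
#' @param tau consensus threshold (default 0.5).
#' @param algorithm,n_runs,max_iter,seed passed to [consensus_partition()]
#'   for the re-clustering of the agreement graph.
#' @return the multi-network `partition`; attribute `cross_layer_matrix`
#'   holds the initial cross-layer consensus matrix.
#' @export
multinetwork_consensus <- function(layer_partitions, tau = 0.5,
                                   algorithm = "louvain", n_runs = 100,
                                   max_iter = 20, seed = NULL) {
  if (length(layer_partitions) < 2)
    stop("cross-layer consensus needs >= 2 layer partitions")
  D <- consensus_matrix(layer_partitions)
  if (.is_block_diagonal(D)) {
    out <- .partition_from_binary(D)      # all layers already agree
    attr(out, "converged") <- TRUE
  } else {
    g <- .graph_from_consensus(D, tau)
    out <- consensus_partition(g, algorithm = algorithm, n_runs = n_runs,
                               tau = tau, max_iter = max_iter, seed = seed)
  }
  attr(out, "cross_layer_matrix") <- D
  out
}

#' Per-layer consensus partitions and cross-layer consensus in one call
#'
#' The complete detection stage: optionally disparity-filter the dense
#' layers at `alpha`, compute each layer's consensus partition, then the
#' cross-layer consensus.
#'
#' @param multinet a `multinet` object.
#' @param alpha scalar or named per-layer significance level for the
#'   disparity filter; `NULL` skips filtering.
#' @param filter_layers names of layers to filter; default all layers except
#'   `ppi` (the validated-interaction layer is left intact).
#' @param algorithm,n_runs,tau,max_iter,seed consensus configuration.
#' @return list with `layer_partitions`, `partition` (cross-layer) and
#'   `filtered` (the filtered multi-network).
#' @export
detect_multinetwork_communities <- function(multinet, alpha = NULL,
                                            filter_layers = NULL,
                                            algorithm = "louvain",
                                            n_runs = 100, tau = 0.5,
                                            max_iter = 20, seed = NULL) {
  lnames <- names(multinet)
  if (is.null(filter_layers)) filter_layers <- setdiff(lnames, "ppi")
  filtered <- multinet
  if (!is.null(alpha)) {
    for (nm in intersect(filter_layers, lnames)) {
      a <- if (length(alpha) > 1) alpha[[nm]] else alpha
      filtered[[nm]] <- disparity_filter(multinet[[nm]], a)
    }
  }
  seeds <- spawn_seeds(seed, length(lnames) + 1)
  layer_parts <- lapply(seq_along(lnames), function(i)
    consensus_partition(filtered[[i]], algorithm = algorithm,
                        n_runs = n_runs, tau = tau, max_iter = max_iter,
                        seed = seeds[i]))
  names(layer_parts) <- lnames
  part <- multinetwork_consensus(layer_parts, tau = tau,
                                 algorithm = algorithm, n_runs = n_runs,
                                 max_iter = max_iter,
                                 seed = seeds[length(seeds)])
  list(layer_partitions = layer_parts, partition = part, filtered = filtered)
}

#' Reduce an overlapping cover to a crisp partition
#'
#' Algorithms that emit overlapping modules (e.g. OSLOM) are reduced for the
#' crisp consensus machinery: every multiply-assigned node goes to its
#' largest containing module (ties to the lexicographically smallest module
#' id); nodes in no module become singletons.
#'
#' @param cover named list of node-id vectors (modules, possibly
#'   overlapping).
#' @param nodes full node set.
#' @return a `partition` over `nodes`.
#' @export
cover_to_partition <- function(cover, nodes) {
  sizes <- vapply(cover, length, 0L)
  ord <- order(-sizes, names(cover))    # largest first, then lexicographic
  memb <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  for (i in ord) {
    hit <- intersect(cover[[i]], nodes[is.na(memb)])
    memb[hit] <- names(cover)[i]
  }
  homeless <- is.na(memb)
  memb[homeless] <- paste0(".singleton.", nodes[homeless])
  as_partition(memb)
}

#' Write a consensus matrix as sparse triplet TSV
#' @param D consensus matrix.
#' @param path output path.
#' @export
write_consensus_matrix <- function(D, path) {
  idx <- which(upper.tri(D) & D > 0, arr.ind = TRUE)
  df <- data.frame(gene1 = rownames(D)[idx[, 1]],
                   gene2 = colnames(D)[idx[, 2]],
                   frequency = D[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
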