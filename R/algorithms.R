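.algorithms <- new.env(parent = emptyenv())

#' Register a community detection algorithm
#'
#' The consensus machinery is algorithm-agnostic: any function mapping a
#' weighted igraph graph and an integer seed to a membership vector (named by
#' node, arbitrary integer labels) can be plugged in.  Built-ins `louvain`
#' (multilevel modularity optimization) and `labelprop` (label propagation)
#' are registered at load time.
#'
#' @param name algorithm name used in [detect_communities()].
#' @param fn `function(graph, seed)` returning a membership vector named by
#'   vertex.
#' @export
register_community_algorithm <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  assign(name, fn, envir = .algorithms)
  invisible(name)
}

#' Names of the registered community detection algorithms
#' @return character vector.
#' @export
community_algorithms <- function() sort(ls(.algorithms))

#' Adapter for an external community detection binary
#'
#' Wraps a command implementing the subprocess contract
#' `command <edgelist.tsv> <membership.tsv> <seed>`: the edge list is written
#' as `from<TAB>to<TAB>weight`, and the command must write a two-column
#' `node<TAB>community` file.  This is how algorithms whose internals are not
#' re-implemented here (e.g. Infomap, OSLOM, simulated-annealing modularity)
#' are attached; register the result with [register_community_algorithm()].
#'
#' @param command path to the executable.
#' @return `function(graph, seed)` suitable for registration.
#' @export
external_algorithm_adapter <- function(command) {
  force(command)
  function(graph, seed) {
    edges <- tempfile(fileext = ".tsv")
    memb <- tempfile(fileext = ".tsv")
    on.exit(unlink(c(edges, memb)))
    el <- igraph::as_data_frame(graph, what = "edges")
    if (!"weight" %in% names(el)) el$weight <- 1
    utils::write.table(el[, c("from", "to", "weight")], edges, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    status <- system2(command, c(edges, memb, as.character(seed)))
    if (status != 0) stop("external algorithm '", command, "' failed")
    df <- utils::read.delim(memb, header = FALSE, stringsAsFactors = FALSE)
    m <- stats::setNames(as.integer(factor(df[[2]])), as.character(df[[1]]))
    missing <- setdiff(igraph::V(graph)$name, names(m))
    if (length(missing) > 0)   # homeless nodes become singletons
      m <- c(m, stats::setNames(max(m, 0) + seq_along(missing), missing))
    m[igraph::V(graph)$name]
  }
}

.builtin_louvain <- function(graph, seed) {
  if (!is.null(seed)) set.seed(seed)
  comm <- igraph::cluster_louvain(graph, weights = igraph::E(graph)$weight)
  stats::setNames(as.integer(igraph::membership(comm)), igraph::V(graph)$name)
}

.builtin_labelprop <- function(graph, seed) {
  if (!is.null(seed)) set.seed(seed)
  comm <- igraph::cluster_label_prop(graph, weights = igraph::E(graph)$weight)
  stats::setNames(as.integer(igraph::membership(comm)), igraph::V(graph)$name)
}

.onLoad <- function(libname, pkgname) {
  register_community_algorithm("louvain", .builtin_louvain)
  register_community_algorithm("labelprop", .builtin_labelprop)
}

#' Detect communities in a single layer
#'
#' Runs one (stochastic) community detection pass.  Edge weights are passed
#' to the algorithm; a graph with no edges decomposes into singletons.
#'
#' @param layer weighted layer graph.
#' @param algorithm registered algorithm name (see
#'   [community_algorithms()]).
#' @param seed integer seed for this run (NULL = current RNG state).
#' @return a `partition`: named integer membership vector with contiguous
#'   labels.
#' @export
detect_communities <- function(layer, algorithm = "louvain", seed = NULL) {
  if (!algorithm %in% ls(.algorithms))
    stop("unknown algorithm '", algorithm, "'; registered: ",
         paste(community_algorithms(), collapse = ", "))
  fn <- get(algorithm, envir = .algorithms)
  as_partition(fn(layer, seed))
}

#' Construct / canonicalize a partition
#'
#' A partition is a named integer vector assigning every node exactly one
#' community; canonical form renumbers labels 1..k in order of first
#' appearance so label identity is irrelevant.
#'
#' @param membership named vector (labels of any type).
#' @return object of class `partition`.
#' @export
as_partition <- function(membership) {
  if (is.null(names(membership))) stop("partition must be named by node id")
  if (any(is.na(membership))) stop("partition contains unassigned nodes")
  labels <- as.integer(factor(as.character(membership),
                              levels = unique(as.character(membership))))
  structure(stats::setNames(labels, names(membership)), class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition: %d nodes in %d communities\n",
              length(x), length(unique(unclass(x)))))
  invisible(x)
}

#' Number of communities in a partition
#' @param partition a `partition`.
#' @return integer count.
#' @export
n_communities <- function(partition) length(unique(unclass(partition)))

#' Community membership as a list of gene sets
#' @param partition a `partition`.
#' @return named list, one character vector of node ids per community.
#' @export
partition_to_sets <- function(partition) {
  split(names(partition), unclass(partition))
}

#' Read / write a partition as two-column TSV (gene, community_id)
#' @param path file path.
#' @rdname partition_io
#' @export
read_partition <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  as_partition(stats::setNames(df[[2]], as.character(df[[1]])))
}

#' @param partition partition to write.
#' @rdname partition_io
#' @export
write_partition <- function(partition, path) {
  utils::write.table(
    data.frame(gene = names(partition), community_id = unclass(partition)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
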