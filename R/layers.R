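#' Construct a weighted layer graph
#'
#' A layer is an undirected, simple [igraph][igraph::igraph-package] graph
#' with positive edge weights and a `layer_name` graph attribute.  Nodes with
#' no edges may be supplied through `nodes` and are retained as isolates.
#'
#' @param edges data frame with columns `from`, `to`, `weight` (weight may be
#'   omitted, defaulting to 1, e.g. for PPI layers).
#' @param nodes optional character vector of node ids (superset of the edge
#'   endpoints).
#' @param name layer name, one of `expression`, `tf`, `mirna`, `ppi` or any
#'   user label.
#' @return igraph object with vertex names and `weight` edge attribute.
#' @export
weighted_layer <- function(edges, nodes = NULL, name = "layer") {
  if (nrow(edges) > 0) {
    from <- as.character(edges[[1]])
    to <- as.character(edges[[2]])
    w <- if (ncol(edges) >= 3) as.numeric(edges[[3]]) else rep(1, nrow(edges))
    if (any(!is.finite(w)) || any(w <= 0)) stop("edge weights must be positive")
    if (any(from == to)) stop("self-loops are not allowed in a layer")
    verts <- sort(unique(c(from, to, as.character(nodes))))
    g <- igraph::graph_from_data_frame(
      data.frame(from = from, to = to, weight = w, stringsAsFactors = FALSE),
      directed = FALSE, vertices = verts)
    if (igraph::any_multiple(g)) stop("duplicate edges in layer input")
  } else {
    g <- igraph::make_empty_graph(directed = FALSE) +
      igraph::vertices(sort(unique(as.character(nodes))))
  }
  igraph::graph_attr(g, "layer_name") <- name
  g
}

#' Layer name accessor
#' @param layer a layer graph.
#' @return the `layer_name` attribute (or "layer").
#' @export
layer_name <- function(layer) {
  igraph::graph_attr(layer, "layer_name") %||% "layer"
}

#' Build the mutual-information co-expression layer
#'
#' Computes pairwise MI between all genes of a preprocessed (log2) expression
#' matrix, producing a complete weighted graph.  MI values that underflow to
#' zero are floored at machine epsilon so the graph stays complete with
#' strictly positive weights, as the downstream disparity filter requires.
#'
#' @param mat preprocessed expression matrix (genes x samples, log2 scale).
#' @inheritParams mutual_information
#' @return complete weighted layer named `expression`.
#' @export
build_expression_layer <- function(mat, bins = ceiling(sqrt(ncol(mat)))) {
  if (nrow(mat) < 3) stop("co-expression layer needs >= 3 genes")
  if (is.null(rownames(mat))) stop("expression matrix must have gene rownames")
  mi <- mi_matrix(mat, bins = bins)
  mi <- pmax(mi, .Machine$double.eps)
  diag(mi) <- 0
  g <- igraph::graph_from_adjacency_matrix(mi, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::graph_attr(g, "layer_name") <- "expression"
  g
}

#' Read a regulator-to-target table
#'
#' @param path TSV with header columns `regulator`, `target` and, for miRNA
#'   tables, `source` (the originating database).
#' @return data frame with those columns, duplicates dropped.
#' @export
read_regulator_targets <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("regulator", "target")
  if (!all(need %in% names(df)))
    stop("regulator table needs columns: regulator, target[, source]")
  keep <- intersect(c("regulator", "target", "source"), names(df))
  unique(df[, keep, drop = FALSE])
}

#' Keep miRNA-target interactions supported by at least two databases
#'
#' Interactions predicted by a single source database are discarded; the
#' consensus table drops the source column and holds unique
#' (regulator, target) pairs supported by two or more distinct databases.
#'
#' @param table data frame with columns `regulator`, `target`, `source`.
#' @return data frame with columns `regulator`, `target`.
#' @export
mirna_consensus_filter <- function(table) {
  if (!"source" %in% names(table) || any(is.na(table$source)) ||
      any(!nzchar(as.character(table$source))))
    stop("miRNA table must carry a populated 'source' database column")
  key <- paste(table$regulator, table$target, sep = "\r")
  nsrc <- tapply(as.character(table$source), key,
                 function(s) length(unique(s)))
  keep <- names(nsrc)[nsrc >= 2]
  if (length(keep) == 0)
    return(data.frame(regulator = character(), target = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(keep, "\r", fixed = TRUE)
  out <- data.frame(regulator = vapply(parts, `[[`, "", 1),
                    target = vapply(parts, `[[`, "", 2),
                    stringsAsFactors = FALSE)
  out[order(out$regulator, out$target), , drop = FALSE]
}

#' One-mode co-targeting projection of a regulator-target table
#'
#' Projects the bipartite regulator/target graph onto the targets: two genes
#' are linked when they share at least one regulator, and the edge weight is
#' the number of shared regulators (a positive integer).  Equivalent to the
#' off-diagonal of \eqn{A^T A} for the bipartite 0/1 incidence matrix A.
#'
#' @param table data frame with columns `regulator`, `target` (a `source`
#'   column, if present, is ignored; run [mirna_consensus_filter()] first for
#'   miRNA tables).
#' @param name layer name for the result (default `"cotargeting"`).
#' @return weighted layer over the target genes.
#' @export
co_targeting_projection <- function(table, name = "cotargeting") {
  if (nrow(table) == 0) stop("empty regulator-target table")
  reg <- as.character(table$regulator)
  tgt <- as.character(table$target)
  pairs <- unique(data.frame(reg = reg, tgt = tgt, stringsAsFactors = FALSE))
  regs <- sort(unique(pairs$reg))
  tgts <- sort(unique(pairs$tgt))
  A <- Matrix::sparseMatrix(i = match(pairs$reg, regs),
                            j = match(pairs$tgt, tgts),
                            x = 1, dims = c(length(regs), length(tgts)))
  W <- Matrix::crossprod(A)                       # targets x targets
  W <- Matrix::triu(W, k = 1)
  idx <- Matrix::which(W > 0, arr.ind = TRUE)
  edges <- data.frame(from = tgts[idx[, 1]], to = tgts[idx[, 2]],
                      weight = W[idx], stringsAsFactors = FALSE)
  weighted_layer(edges, nodes = tgts, name = name)
}

#' Restrict layers to their common node set
#'
#' Induces every layer on the intersection of all layers' node sets, the
#' step that turns independently constructed layers into a multi-network.
#' Nodes isolated after induction are retained so all layers share one
#' identical, sorted node set.
#'
#' @param layers list of weighted layers (>= 2).
#' @return object of class `multinet`: a named list of layer graphs on the
#'   identical node set.
#' @export
intersect_to_multinetwork <- function(layers) {
  if (length(layers) < 2) stop("a multi-network needs >= 2 layers")
  nodesets <- lapply(layers, function(g) igraph::V(g)$name)
  common <- sort(Reduce(intersect, nodesets))
  if (length(common) == 0) stop("layers share no common nodes")
  out <- lapply(layers, function(g) {
    sub <- igraph::induced_subgraph(g, common)
    igraph::permute(sub, match(igraph::V(sub)$name, common))
  })
  names(out) <- vapply(layers, layer_name, "")
  structure(out, class = "multinet")
}

#' Node ids of a multi-network
#' @param multinet a `multinet` object.
#' @return sorted character vector of the shared node ids.
#' @export
multinet_nodes <- function(multinet) {
  igraph::V(multinet[[1]])$name
}

#' @export
print.multinet <- function(x, ...) {
  cat(sprintf("multi-network: %d layers on %d shared genes\n",
              length(x), length(multinet_nodes(x))))
  for (nm in names(x))
    cat(sprintf("  %-12s %7d edges\n", nm, igraph::ecount(x[[nm]])))
  invisible(x)
}

#' Read / write a weighted edge-list layer
#'
#' Layers are serialized as TSV `gene1 <TAB> gene2 <TAB> weight` with a
#' header row naming the layer (`# layer: <name>` comment line followed by
#' column names).
#'
#' @param path file path.
#' @rdname layer_io
#' @export
read_layer <- function(path) {
  first <- readLines(path, n = 1)
  name <- sub("^#\\s*layer:\\s*", "", first)
  if (identical(name, first)) name <- "layer"
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  nodes <- attr(df, "nodes")
  weighted_layer(df, name = name)
}

#' @param layer layer graph to write.
#' @rdname layer_io
#' @export
write_layer <- function(layer, path) {
  el <- igraph::as_data_frame(layer, what = "edges")
  if (!"weight" %in% names(el)) el$weight <- 1
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# layer: %s", layer_name(layer)), con)
  utils::write.table(el[, c("from", "to", "weight")], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
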