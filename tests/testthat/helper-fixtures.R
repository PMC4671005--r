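# Shared fixtures built in code: tiny graphs, partitions and matrices.

# Two k-cliques joined by a single bridge edge.
two_cliques_graph <- function(k = 10) {
  ids <- c(sprintf("a%02d", seq_len(k)), sprintf("b%02d", seq_len(k)))
  cl <- function(v) t(combn(v, 2))
  el <- rbind(cl(ids[1:k]), cl(ids[(k + 1):(2 * k)]), c(ids[1], ids[k + 1]))
  weighted_layer(data.frame(from = el[, 1], to = el[, 2], weight = 1),
                 name = "cliques")
}

# Planted 4-block SBM (igraph) with named vertices and its truth partition.
planted_sbm <- function(seed, n_blocks = 4, block_size = 25, p_in = 0.3,
                        p_out = 0.02) {
  set.seed(seed)
  n <- n_blocks * block_size
  pref <- matrix(p_out, n_blocks, n_blocks)
  diag(pref) <- p_in
  g <- igraph::sample_sbm(n, pref.matrix = pref,
                          block.sizes = rep(block_size, n_blocks))
  igraph::V(g)$name <- sprintf("v%03d", seq_len(n))
  igraph::E(g)$weight <- 1
  truth <- as_partition(stats::setNames(rep(seq_len(n_blocks),
                                            each = block_size),
                                        igraph::V(g)$name))
  list(graph = g, truth = truth)
}

random_partition <- function(nodes, k, seed) {
  set.seed(seed)
  as_partition(stats::setNames(sample.int(k, length(nodes), replace = TRUE),
                               nodes))
}

# Random weighted graph with heavy-tailed (log-normal) weights.
heavy_tailed_graph <- function(n = 50, p = 0.3, seed = 1) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("h%02d", seq_len(n))
  igraph::E(g)$weight <- exp(stats::rnorm(igraph::ecount(g), sd = 1.5))
  igraph::graph_attr(g, "layer_name") <- "heavy"
  g
}
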