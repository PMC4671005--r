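# Brute-force co-assignment counting oracle.
consensus_oracle <- function(partitions) {
  nodes <- sort(names(partitions[[1]]))
  D <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      together <- sum(vapply(partitions, function(p)
        unclass(p)[nodes[i]] == unclass(p)[nodes[j]], TRUE))
      D[i, j] <- together / length(partitions)
    }
  }
  D
}

test_that("both built-in algorithms resolve two joined cliques", {
  g <- two_cliques_graph(10)
  truth <- as_partition(setNames(rep(1:2, each = 10), igraph::V(g)$name))
  for (alg in c("louvain", "labelprop")) {
    p <- detect_communities(g, alg, seed = 42)
    expect_equal(nmi(p, truth), 1)
  }
  # complete graph collapses to a single community
  cg <- weighted_layer(data.frame(from = t(combn(letters[1:8], 2))[, 1],
                                  to = t(combn(letters[1:8], 2))[, 2],
                                  weight = 1))
  expect_equal(n_communities(detect_communities(cg, "louvain", seed = 1)), 1)
  expect_error(detect_communities(g, "no-such-algorithm"), "unknown")
})

test_that("an edgeless graph decomposes into singletons", {
  g <- weighted_layer(data.frame(from = character(), to = character(),
                                 weight = numeric()),
                      nodes = paste0("x", 1:5))
  p <- detect_communities(g, "louvain", seed = 1)
  expect_equal(n_communities(p), 5)
})

test_that("Louvain recovers planted SBM blocks", {
  nmis <- sapply(1:20, function(s) {
    sbm <- planted_sbm(seed = s)
    nmi(detect_communities(sbm$graph, "louvain", seed = s), sbm$truth)
  })
  expect_gte(median(nmis), 0.95)
})

test_that("the consensus matrix counts co-assignments exactly", {
  nodes <- paste0("n", 1:4)
  p1 <- as_partition(setNames(c(1, 1, 2, 2), nodes))
  p2 <- as_partition(setNames(c(1, 2, 2, 2), nodes))
  D <- consensus_matrix(list(p1, p2))
  expect_equal(D["n1", "n2"], 0.5)
  expect_equal(D["n3", "n4"], 1)
  expect_equal(D["n1", "n3"], 0)
  # identical partitions reproduce the blocks as a 0/1 matrix
  Did <- consensus_matrix(list(p1, p1, p1))
  expect_true(all(Did %in% c(0, 1)))
  expect_equal(Did, outer(unclass(p1), unclass(p1), function(a, b)
    (a == b) * 1)[nodes, nodes])
  expect_error(consensus_matrix(list(p1)), ">= 2")
  p3 <- as_partition(setNames(1:3, paste0("m", 1:3)))
  expect_error(consensus_matrix(list(p1, p3)), "different node sets")
})

test_that("consensus matrices match the counting oracle and its invariants", {
  nodes <- sprintf("n%02d", 1:12)
  parts <- lapply(1:10, function(s) random_partition(nodes, 3, seed = s))
  D <- consensus_matrix(parts)
  expect_equal(D, consensus_oracle(parts))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 1))
  expect_true(all(abs(D * 10 - round(D * 10)) < 1e-12))  # 1/n_runs quanta
})

test_that("a deterministic algorithm converges in one consensus round", {
  register_community_algorithm("components", function(graph, seed) {
    setNames(as.integer(igraph::components(graph)$membership),
             igraph::V(graph)$name)
  })
  g <- two_cliques_graph(5)
  g <- igraph::delete_edges(g, igraph::E(g)[igraph::get_edge_ids(
    g, c("a01", "b01"))])
  p <- consensus_partition(g, "components", n_runs = 5, seed = 1)
  expect_true(attr(p, "converged"))
  expect_equal(attr(p, "iterations"), 1)
  expect_equal(nmi(p, detect_communities(g, "components")), 1)
})

test_that("consensus over runs reproduces the clique structure", {
  g <- two_cliques_graph(10)
  truth <- as_partition(setNames(rep(1:2, each = 10), igraph::V(g)$name))
  for (alg in c("louvain", "labelprop")) {
    p <- consensus_partition(g, alg, n_runs = 20, seed = 3)
    expect_equal(nmi(p, truth), 1)
  }
})

test_that("consensus stabilizes label propagation on planted blocks", {
  single <- numeric(20)
  consens <- numeric(20)
  for (s in 1:20) {
    sbm <- planted_sbm(seed = 100 + s)
    single[s] <- nmi(detect_communities(sbm$graph, "labelprop", seed = s),
                     sbm$truth)
    consens[s] <- nmi(consensus_partition(sbm$graph, "labelprop",
                                          n_runs = 30, seed = s),
                      sbm$truth)
  }
  expect_gte(median(consens), median(single))
})

test_that("consensus partitions are invariant to node relabelling", {
  g <- two_cliques_graph(6)
  p1 <- consensus_partition(g, "louvain", n_runs = 10, seed = 5)
  relab <- setNames(sprintf("q%02d", 12:1), igraph::V(g)$name)
  g2 <- g
  igraph::V(g2)$name <- relab[igraph::V(g)$name]
  p2 <- consensus_partition(g2, "louvain", n_runs = 10, seed = 5)
  p2_back <- as_partition(setNames(unclass(p2),
                                   names(relab)[match(names(p2), relab)]))
  expect_equal(nmi(p1, p2_back), 1)
})

test_that("cross-layer consensus honours agreement and quantization", {
  nodes <- sprintf("n%02d", 1:20)
  base <- as_partition(setNames(rep(1:4, each = 5), nodes))
  # all layers identical -> that partition, exactly
  out <- multinetwork_consensus(list(base, base, base, base), seed = 1,
                                n_runs = 10)
  expect_equal(nmi(out, base), 1)
  expect_true(attr(out, "converged"))
  # four mutually random partitions -> entries quantized to quarters
  parts <- lapply(1:4, function(s) random_partition(nodes, 5, seed = 20 + s))
  out2 <- multinetwork_consensus(parts, seed = 2, n_runs = 10)
  D <- attr(out2, "cross_layer_matrix")
  expect_true(all(D %in% c(0, 0.25, 0.5, 0.75, 1)))
  expect_error(multinetwork_consensus(list(base)), ">= 2")
})

test_that("three informative layers outvote one random layer", {
  nodes <- sprintf("n%03d", 1:100)
  truth <- as_partition(setNames(rep(1:4, each = 25), nodes))
  rnd <- random_partition(nodes, 8, seed = 77)
  out <- multinetwork_consensus(list(truth, truth, truth, rnd), tau = 0.5,
                                n_runs = 20, seed = 5)
  expect_gte(nmi(out, truth), 0.9)
})

test_that("NMI agrees with hand-computed and independent references", {
  nodes <- c("A", "B", "C", "D", "E", "F")
  a <- as_partition(setNames(c(1, 1, 2, 2, 3, 3), nodes))
  b <- as_partition(setNames(c(1, 1, 2, 2, 2, 2), nodes))
  # contingency: [2,0;0,2;0,2]; I, H computed from those counts
  pxy <- matrix(c(2, 0, 0, 2, 0, 2), ncol = 2, byrow = TRUE) / 6
  px <- rowSums(pxy); py <- colSums(pxy)
  I <- sum(pxy[pxy > 0] * log(pxy[pxy > 0] /
                                outer(px, py)[pxy > 0]))
  expected <- I / ((-sum(px * log(px)) - sum(py * log(py))) / 2)
  expect_equal(nmi(a, b), expected)
  expect_equal(nmi(a, b), igraph::compare(unclass(a)[nodes],
                                          unclass(b)[nodes],
                                          method = "nmi"))
  expect_equal(nmi(a, a), 1)
  one_block <- as_partition(setNames(rep(1, 6), nodes))
  expect_equal(nmi(a, one_block), 0)
  expect_equal(nmi(one_block, one_block), 1)
})

test_that("NMI is symmetric, label-invariant and matches igraph on random cases", {
  nodes <- sprintf("n%02d", 1:30)
  for (s in 1:10) {
    a <- random_partition(nodes, 4, seed = s)
    b <- random_partition(nodes, 6, seed = 50 + s)
    expect_equal(nmi(a, b), nmi(b, a))
    expect_equal(nmi(a, b),
                 igraph::compare(unclass(a)[nodes], unclass(b)[nodes],
                                 method = "nmi"),
                 tolerance = 1e-12)
    shuffled <- as_partition(setNames(match(unclass(a), sample(4)), nodes))
    expect_equal(nmi(a, shuffled), 1)
  }
})

test_that("the Rand index counts pairwise agreements", {
  nodes <- paste0("n", 1:4)
  a <- as_partition(setNames(c(1, 1, 2, 2), nodes))
  b <- as_partition(setNames(c(1, 1, 1, 2), nodes))
  # pairs: 12 same/same, 34 diff/same->disagree? enumerate: agreements are
  # (1,2) together/together, (1,4),(2,4) apart/apart, (1,3),(2,3) apart/
  # together disagree, (3,4) together/apart disagree -> 3/6
  expect_equal(rand_index(a, b), 0.5)
  expect_equal(rand_index(a, a), 1)
})

test_that("overlapping covers reduce to crisp partitions deterministically", {
  nodes <- paste0("g", 1:6)
  cover <- list(m1 = c("g1", "g2", "g3"), m2 = c("g3", "g4"),
                m3 = c("g4", "g5"))
  p <- cover_to_partition(cover, nodes)
  sets <- partition_to_sets(p)
  memb <- setNames(unclass(p), names(p))
  expect_equal(memb[["g3"]], memb[["g1"]])   # largest module wins
  expect_true(memb[["g6"]] != memb[["g1"]])  # homeless -> singleton
  # tie between equal-sized modules goes to the lexicographically smaller
  cover2 <- list(z = c("g1", "g2"), a = c("g2", "g3"))
  p2 <- cover_to_partition(cover2, paste0("g", 1:3))
  memb2 <- setNames(unclass(p2), names(p2))
  expect_equal(memb2[["g2"]], memb2[["g3"]])
})
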