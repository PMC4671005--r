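# Exhaustive oracle: enumerate every draw of |community| genes from the
# universe and count those whose overlap with the set reaches the observed.
hyper_enum <- function(N, K, n, k) {
  draws <- combn(N, n)
  succ <- seq_len(K)
  mean(apply(draws, 2, function(d) sum(d %in% succ) >= k))
}

test_that("hypergeometric enrichment matches closed forms", {
  u <- paste0("g", 1:10)
  res <- hypergeom_enrichment(u[1:5], u[1:5], u)
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(sort(res$intersection), u[1:5])
  # zero overlap is never significant
  res0 <- hypergeom_enrichment(u[1:3], u[4:6], u)
  expect_equal(res0$p, 1)
  # the K = 2 closed form at a realistic geometry:
  # P(both successes drawn) = n(n-1) / (N(N-1))
  big <- paste0("x", seq_len(5307))
  res2 <- hypergeom_enrichment(big[1:119], big[1:2], big)
  expect_equal(res2$p, (119 * 118) / (5307 * 5306), tolerance = 1e-9)
  expect_equal(res2$p, 4.99e-4, tolerance = 0.01)
  expect_error(hypergeom_enrichment(character(), u[1:2], u), "nonempty")
  expect_error(hypergeom_enrichment(c("zz"), u[1:2], u), "subsets")
})

test_that("hypergeometric tails equal exhaustive enumeration (N <= 15)", {
  u <- paste0("g", 1:12)
  cases <- list(c(K = 4, n = 5), c(K = 6, n = 3), c(K = 3, n = 7))
  for (cs in cases) {
    K <- cs[["K"]]; n <- cs[["n"]]
    for (k in 0:min(K, n)) {
      outside <- if (n - k > 0) seq.int(K + 1, K + n - k) else integer()
      comm <- u[c(seq_len(k), outside)]
      res <- hypergeom_enrichment(comm, u[seq_len(K)], u)
      expect_equal(res$p, hyper_enum(12, K, n, k), tolerance = 1e-9)
    }
  }
})

test_that("Benjamini-Hochberg adjustment applies the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  # order invariance and monotonicity on sorted values
  set.seed(2)
  p <- runif(20)
  ord <- sample(20)
  expect_equal(bh_adjust(p)[ord], bh_adjust(p[ord]))
  expect_true(all(diff(sort(bh_adjust(p))) >= -1e-15))
  expect_true(all(bh_adjust(p) >= p))
})

test_that("functional homogeneity flags communities matching gene sets", {
  u <- sprintf("g%03d", 1:100)
  part <- as_partition(setNames(rep(1:4, each = 25), u))
  sets <- gene_set_collection(split(u, rep(1:4, each = 25)), "GO")
  hom <- functional_homogeneity(part, sets, universe = u)
  expect_equal(hom$fraction, 1)
  # one community coincides with a set, the other matches nothing
  part2 <- as_partition(setNames(rep(1:2, each = 50), u))
  sets2 <- gene_set_collection(list(hit = u[1:50]), "pathway")
  hom2 <- functional_homogeneity(part2, sets2, universe = u)
  expect_equal(hom2$fraction, 0.5)
  expect_true(hom2$flags[["1"]])
  expect_false(hom2$flags[["2"]])
  expect_error(functional_homogeneity(part, list()), "no gene-set")
})

test_that("false-positive rate of homogeneity stays near the FDR level", {
  u <- sprintf("g%03d", 1:100)
  fracs <- sapply(1:20, function(s) {
    set.seed(s)
    part <- as_partition(setNames(rep(1:5, each = 20)[sample(100)], u))
    sets <- gene_set_collection(
      setNames(lapply(1:6, function(i) sample(u, 15)), paste0("s", 1:6)),
      "GO")
    functional_homogeneity(part, sets, universe = u, fdr = 0.05)$fraction
  })
  expect_lt(mean(fracs), 0.25)   # random sets rarely look homogeneous
})

test_that("differential-expression criteria have their closed forms", {
  genes <- c("up", "down")
  mat <- rbind(up = c(2, 2, 1, 1), down = c(1, 1, 2, 2))
  colnames(mat) <- paste0("s", 1:4)
  cond <- setNames(c("tumor", "tumor", "normal", "normal"), colnames(mat))
  cr <- diff_expression_criteria(genes, mat, cond)
  expect_equal(cr[["c1"]], 0)                 # +1 and -1 cancel
  expect_equal(cr[["c3"]], sd(c(1, -1)))      # sample sd = sqrt(2)
  # uniform +2 shift, no variance
  mat2 <- rbind(a = c(5, 5, 3, 3), b = c(6, 6, 4, 4))
  colnames(mat2) <- names(cond)
  cr2 <- diff_expression_criteria(c("a", "b"), mat2, cond)
  expect_equal(cr2[["c1"]], 2)
  expect_equal(cr2[["c3"]], 0)
  expect_error(diff_expression_criteria(c("a", "zz"), mat2, cond), "zz")
})

test_that("a planted up-regulated module is detected decisively", {
  d <- planted_design(n_genes = 40, block_sizes = c(20, 20),
                      rho_within = 0, n_tumor = 50, n_normal = 50,
                      fold_changes = c(1, 0), fc_sd = 0.2, seed = 13)
  sim <- simulate_expression(d)
  mat <- log2(sim$values)
  comm <- d$genes[d$block == 1]
  cr <- diff_expression_criteria(comm, mat, sim$condition)
  expect_gte(cr[["c1"]], 0.8)
  expect_lte(cr[["c1"]], 1.2)
  expect_lt(cr[["c2"]], 1e-6)
  expect_gt(cr[["c3"]], 0.05)
  expect_lt(cr[["c3"]], 0.4)                  # near the planted 0.2 spread
})

test_that("the criteria respect shift and label-swap invariances", {
  d <- planted_design(n_genes = 30, block_sizes = c(15, 15),
                      rho_within = 0.5, n_tumor = 20, n_normal = 20,
                      fold_changes = c(0.7, -0.3), seed = 19)
  sim <- simulate_expression(d)
  mat <- log2(sim$values)
  comm <- d$genes[1:15]
  base <- diff_expression_criteria(comm, mat, sim$condition)
  shifted <- diff_expression_criteria(comm, mat + 3.7, sim$condition)
  expect_equal(shifted[["c1"]], base[["c1"]])
  expect_equal(shifted[["c3"]], base[["c3"]])
  swapped_cond <- setNames(ifelse(sim$condition == "tumor", "normal",
                                  "tumor"), names(sim$condition))
  swapped <- diff_expression_criteria(comm, mat, swapped_cond)
  expect_equal(swapped[["c1"]], base[["c1"]])  # |mean| is sign-blind
  expect_equal(swapped[["c3"]], base[["c3"]])
  expect_equal(swapped[["c2"]], base[["c2"]], tolerance = 1e-12)
})

test_that("tumor-specific category subtraction is exact set algebra", {
  mk <- function(sets, cats, p) {
    data.frame(community = "1", set = sets, category = cats,
               p_raw = p, p_adjust = p, stringsAsFactors = FALSE)
  }
  tm <- mk(c("a", "b"), c("GO", "pathway"), c(1e-6, 1e-3))
  nm <- mk("b", "pathway", 1e-3)
  te <- mk("c", "GO", 1e-4)
  ne <- mk("c", "GO", 1e-4)
  out <- tumor_specific_categories(tm, nm, te, ne)
  expect_equal(out$categories$set, "a")
  expect_equal(out$categories$category, "GO")
  expect_equal(out$radar$set, "a")            # p = 1e-6 < 1e-5
  expect_equal(out$radar$reciprocal_p, 1e6)
  # sig(TM) == sig(TE) empties the result
  out2 <- tumor_specific_categories(tm, mk("zz", "GO", 1),
                                    tm, mk("zz", "GO", 1))
  expect_equal(nrow(out2$categories), 0)
  # inconsistent category tags are rejected
  bad <- mk("a", "pathway", 0.5)
  expect_error(tumor_specific_categories(tm, nm, te, bad), "inconsistent")
})

test_that("category subtraction matches a set oracle on random inputs", {
  set.seed(33)
  cats <- sprintf("cat%02d", 1:50)
  tags <- sample(c("GO", "pathway", "chromosomal_location",
                   "motif_TF_miRNA"), 50, replace = TRUE)
  mk_random <- function(seed) {
    set.seed(seed)
    sel <- sample(50, 20)
    data.frame(community = "1", set = cats[sel], category = tags[sel],
               p_raw = runif(20, 1e-8, 0.04),
               p_adjust = runif(20, 1e-8, 0.04), stringsAsFactors = FALSE)
  }
  tm <- mk_random(1); nm <- mk_random(2); te <- mk_random(3)
  ne <- mk_random(4)
  out <- tumor_specific_categories(tm, nm, te, ne)
  oracle <- setdiff(setdiff(tm$set, nm$set), setdiff(te$set, ne$set))
  expect_setequal(out$categories$set, oracle)
  # pure set algebra: recomputing changes nothing (idempotent inputs)
  out2 <- tumor_specific_categories(tm, nm, te, ne)
  expect_identical(out$categories, out2$categories)
})

test_that("signature intersection reports the Table-shaped family", {
  set.seed(44)
  u <- sprintf("g%03d", 1:200)
  part <- as_partition(setNames(rep(1:10, each = 20), u))
  sigs <- gene_set_collection(
    list(sigA = u[1:12],                       # sits inside community 1
         sigB = sample(u, 15),
         sigC = sample(u, 8)),
    "signature")
  tab <- signature_intersection(part, sigs, universe = u)
  expect_equal(nrow(tab), 30)
  # per-cell closed-form oracle
  for (r in sample(nrow(tab), 10)) {
    row <- tab[r, ]
    comm <- u[unclass(part) == as.integer(row$communityID)]
    expect_equal(row$p_raw,
                 phyper(row$intersection - 1, row$signaturesize,
                        200 - row$signaturesize, row$communitysize,
                        lower.tail = FALSE), tolerance = 1e-12)
  }
  # an exact-match signature attains the family's smallest raw p
  best <- tab[tab$class == "sigA", ]
  expect_equal(best$communityID[which.min(best$p_raw)], "1")
  expect_equal(min(tab$p_raw), min(best$p_raw))
  # BH never decreases a p-value
  expect_true(all(tab$p_value >= tab$p_raw - 1e-15))
  # disjoint signature: all raw p = 1
  sigd <- gene_set_collection(list(none = u[1:5]), "signature")
  part2 <- as_partition(setNames(rep(1:2, each = 100), u))
  # community 2 misses u[1:5]; its row must be p_raw = 1
  tab2 <- signature_intersection(part2, sigd, universe = u)
  expect_equal(tab2$p_raw[tab2$communityID == "2"], 1)
  expect_error(signature_intersection(part, gene_set_collection(
    list(x = u[1:3]), "GO")), "signature")
})
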