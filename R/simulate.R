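#' Planted multi-network design
#'
#' Parameters of the synthetic generator that produces every pipeline input
#' with a common planted block structure: block-correlated expression,
#' regulator tables whose target sets concentrate within blocks, an SBM PPI
#' and a gold standard enriched within blocks.  The planted partition is the
#' ground truth for recovery checks.
#'
#' Expression follows a factor model on the log2 scale: gene g in block b of
#' sample s is
#' `sqrt(rho_between)*global_s + sqrt(rho_within - rho_between)*factor_bs +
#'  sqrt(1 - rho_within)*noise_gs`, plus, in tumor samples, a per-gene shift
#' drawn once as `N(fold_change_b, fc_sd^2)`; intensities are
#' `2^(baseline + value)` so the preprocessing stage (including the log2
#' transform) applies.
#'
#' @param n_genes total genes (default 400).
#' @param block_sizes integer vector summing to `n_genes` (default four
#'   equal blocks).
#' @param rho_within,rho_between within-/between-block expression
#'   correlation (defaults 0.9 / 0); requires
#'   `0 <= rho_between <= rho_within <= 1` for a valid covariance.
#' @param n_tumor,n_normal samples per condition (defaults 50 / 50).
#' @param fold_changes per-block tumor log2 fold-change shifts (default
#'   `c(1, -1, 0.5, 0)` recycled over blocks).
#' @param fc_sd per-gene standard deviation of the planted shift (default
#'   0.2).
#' @param baseline log2 baseline intensity (default 7).
#' @param regulators_per_block regulators per block for the TF and miRNA
#'   tables (default 20).
#' @param reg_p_in,reg_p_out probability a regulator targets a gene of its
#'   home block / of another block (defaults 0.3 / 0.01).
#' @param ppi_p_in,ppi_p_out SBM edge probabilities of the PPI layer
#'   (defaults 0.15 / 0.005).
#' @param gold_within,gold_between number of gold-standard pairs sampled
#'   within / between blocks (defaults 500 / 50).
#' @param seed master seed.
#' @return object of class `planted_design`.
#' @export
planted_design <- function(n_genes = 400, block_sizes = NULL,
                           rho_within = 0.9, rho_between = 0,
                           n_tumor = 50, n_normal = 50,
                           fold_changes = c(1, -1, 0.5, 0), fc_sd = 0.2,
                           baseline = 7, regulators_per_block = 20,
                           reg_p_in = 0.3, reg_p_out = 0.01,
                           ppi_p_in = 0.15, ppi_p_out = 0.005,
                           gold_within = 500, gold_between = 50,
                           seed = 1) {
  if (is.null(block_sizes)) {
    k <- 4
    block_sizes <- rep(n_genes %/% k, k)
    block_sizes[k] <- n_genes - sum(block_sizes[-k])
  }
  if (sum(block_sizes) != n_genes)
    stop("block sizes must sum to n_genes")
  probs <- c(reg_p_in, reg_p_out, ppi_p_in, ppi_p_out)
  if (any(probs < 0) || any(probs > 1)) stop("probabilities must be in [0,1]")
  if (rho_between < 0 || rho_between > rho_within || rho_within > 1)
    stop("need 0 <= rho_between <= rho_within <= 1 (covariance not PSD)")
  k <- length(block_sizes)
  design <- list(
    n_genes = n_genes, block_sizes = block_sizes,
    rho_within = rho_within, rho_between = rho_between,
    n_tumor = n_tumor, n_normal = n_normal,
    fold_changes = rep_len(fold_changes, k), fc_sd = fc_sd,
    baseline = baseline, regulators_per_block = regulators_per_block,
    reg_p_in = reg_p_in, reg_p_out = reg_p_out,
    ppi_p_in = ppi_p_in, ppi_p_out = ppi_p_out,
    gold_within = gold_within, gold_between = gold_between, seed = seed)
  design$genes <- sprintf("g%04d", seq_len(n_genes))
  design$block <- rep(seq_len(k), block_sizes)
  structure(design, class = "planted_design")
}

#' Ground-truth planted partition of a design
#' @param design a `planted_design`.
#' @return a `partition` assigning each gene to its planted block.
#' @export
planted_truth <- function(design) {
  as_partition(stats::setNames(design$block, design$genes))
}

#' Simulate a block-correlated expression matrix
#'
#' See [planted_design()] for the model.  Output is on the intensity scale
#' (strictly positive), ready for [preprocess_expression()]; take `log2()`
#' of `$values` to recover the simulated log2 matrix exactly.
#'
#' @param design a `planted_design`.
#' @return list with `values` (genes x samples intensity matrix),
#'   `condition` (named tumor/normal vector), `shifts` (per-gene planted
#'   log2 fold change) and `truth` (planted partition).
#' @export
simulate_expression <- function(design) {
  set.seed(design$seed)
  n <- design$n_tumor + design$n_normal
  samples <- c(sprintf("T%03d", seq_len(design$n_tumor)),
               sprintf("N%03d", seq_len(design$n_normal)))
  condition <- stats::setNames(rep(c("tumor", "normal"),
                                   c(design$n_tumor, design$n_normal)),
                               samples)
  g <- design$n_genes
  blk <- design$block
  k <- length(design$block_sizes)
  w_glob <- sqrt(design$rho_between)
  w_blk <- sqrt(design$rho_within - design$rho_between)
  w_noise <- sqrt(1 - design$rho_within)
  global <- stats::rnorm(n)
  factors <- matrix(stats::rnorm(k * n), nrow = k)
  noise <- matrix(stats::rnorm(g * n), nrow = g)
  z <- w_glob * matrix(global, g, n, byrow = TRUE) +
    w_blk * factors[blk, , drop = FALSE] + w_noise * noise
  shifts <- stats::rnorm(g, mean = design$fold_changes[blk], sd = design$fc_sd)
  z[, condition == "tumor"] <- z[, condition == "tumor"] + shifts
  values <- 2^(design$baseline + z)
  dimnames(values) <- list(design$genes, samples)
  list(values = values, condition = condition,
       shifts = stats::setNames(shifts, design$genes),
       truth = planted_truth(design))
}

.simulate_targets <- function(design, prefix) {
  k <- length(design$block_sizes)
  rows <- list()
  for (b in seq_len(k)) {
    for (r in seq_len(design$regulators_per_block)) {
      reg <- sprintf("%s_b%d_r%02d", prefix, b, r)
      p <- ifelse(design$block == b, design$reg_p_in, design$reg_p_out)
      hit <- stats::runif(design$n_genes) < p
      if (any(hit))
        rows[[length(rows) + 1]] <- data.frame(
          regulator = reg, target = design$genes[hit],
          stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate TF and miRNA regulator-target tables
#'
#' Each regulator has a home block and targets its block's genes with
#' `reg_p_in`, other genes with `reg_p_out`.  The miRNA table additionally
#' assigns every interaction to 1-3 of five pseudo-databases (probabilities
#' 0.3/0.4/0.3), so the two-database consensus rule has work to do.
#'
#' @param design a `planted_design`.
#' @return list with `tf` (columns regulator, target) and `mirna` (columns
#'   regulator, target, source).
#' @export
simulate_regulator_tables <- function(design) {
  set.seed(design$seed + 1L)
  tf <- .simulate_targets(design, "TF")
  mir <- .simulate_targets(design, "MIR")
  dbs <- paste0("db", 1:5)
  ndb <- sample(1:3, nrow(mir), replace = TRUE, prob = c(0.3, 0.4, 0.3))
  mirna <- do.call(rbind, lapply(seq_len(nrow(mir)), function(i) {
    data.frame(regulator = mir$regulator[i], target = mir$target[i],
               source = sample(dbs, ndb[i]), stringsAsFactors = FALSE)
  }))
  list(tf = tf, mirna = mirna)
}

#' Simulate the PPI layer and a gold-standard edge set
#'
#' The PPI is a stochastic block model on the planted blocks with unit edge
#' weights.  The gold standard samples `gold_within` distinct within-block
#' pairs and `gold_between` between-block pairs, so the Fisher-enrichment
#' criterion of [select_alpha()] rewards backbones that concentrate within
#' blocks.
#'
#' @param design a `planted_design`.
#' @return list with `ppi` (weighted layer named `ppi`, all weights 1) and
#'   `gold` (data frame gene1, gene2).
#' @export
simulate_ppi_and_gold <- function(design) {
  set.seed(design$seed + 2L)
  g <- design$n_genes
  blk <- design$block
  idx <- which(upper.tri(matrix(0, g, g)), arr.ind = TRUE)
  same <- blk[idx[, 1]] == blk[idx[, 2]]
  p <- ifelse(same, design$ppi_p_in, design$ppi_p_out)
  keep <- stats::runif(nrow(idx)) < p
  edges <- data.frame(from = design$genes[idx[keep, 1]],
                      to = design$genes[idx[keep, 2]],
                      weight = 1, stringsAsFactors = FALSE)
  ppi <- weighted_layer(edges, nodes = design$genes, name = "ppi")
  win <- which(same)
  btw <- which(!same)
  gw <- win[sample.int(length(win), min(design$gold_within, length(win)))]
  gb <- btw[sample.int(length(btw), min(design$gold_between, length(btw)))]
  sel <- c(gw, gb)
  gold <- data.frame(gene1 = design$genes[idx[sel, 1]],
                     gene2 = design$genes[idx[sel, 2]],
                     stringsAsFactors = FALSE)
  list(ppi = ppi, gold = gold)
}

#' Write all simulated pipeline inputs to a directory
#'
#' Emits the five input files in the exact dialects the pipeline reads
#' (expression matrix + condition sidecar, TF table, miRNA table with
#' sources, PPI edge list, gold-standard edge list) plus `truth.tsv`, the
#' planted partition.
#'
#' @param design a `planted_design`.
#' @param dir output directory (created if missing).
#' @return named character vector of the file paths, invisibly.
#' @export
simulate_multinetwork_inputs <- function(design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr <- simulate_expression(design)
  regs <- simulate_regulator_tables(design)
  pg <- simulate_ppi_and_gold(design)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             conditions = file.path(dir, "conditions.tsv"),
             tf = file.path(dir, "tf_targets.tsv"),
             mirna = file.path(dir, "mirna_targets.tsv"),
             ppi = file.path(dir, "ppi.tsv"),
             gold = file.path(dir, "gold.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_expression_matrix(expr$values, paths["expression"])
  utils::write.table(data.frame(sample = names(expr$condition),
                                condition = expr$condition),
                     paths["conditions"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(regs$tf, paths["tf"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(regs$mirna, paths["mirna"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  el <- igraph::as_data_frame(pg$ppi, what = "edges")
  utils::write.table(stats::setNames(el[, c("from", "to")],
                                     c("gene1", "gene2")),
                     paths["ppi"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(pg$gold, paths["gold"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_partition(expr$truth, paths["truth"])
  invisible(paths)
}
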