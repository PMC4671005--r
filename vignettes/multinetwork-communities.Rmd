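---
title: "Methods: gene multi-networks, backbone filtering and consensus communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene multi-networks, backbone filtering and consensus communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

genemux treats a set of genes as the shared node set of four interaction
layers — a *multi-network*: each layer is an undirected weighted graph over
the same genes, and no explicit inter-layer couplings are modelled.

* **Co-expression.** Pairwise mutual information (MI) between preprocessed
  log2 expression profiles, giving a complete weighted graph. MI is
  estimated by equal-frequency (quantile) binning with
  $B = \lceil\sqrt{n_{\mathrm{samples}}}\rceil$ bins per margin and reported
  in bits, so weights are directly comparable with entropies of log2-scale
  data. The estimator is deliberately simple: the complete graph is passed
  to the disparity filter, which consumes relative weights at each node, so
  the uniform positive bias of plug-in MI (which grows with $B^2/n$)
  inflates all edges of a node together and largely cancels in the filter's
  normalized shares.
* **TF and miRNA co-targeting.** One-mode projections of regulator→target
  tables: two genes are linked when they share at least one regulator, with
  integer weight equal to the number of shared regulators (the off-diagonal
  of $A^{\mathsf T}A$ for the bipartite incidence $A$). miRNA interactions
  must be supported by at least two distinct source databases before
  projection; TF tables come from a single source and are used as-is.
* **PPI.** An unweighted (weight 1) edge list of experimentally validated
  interactions.

Layers are built independently and then restricted to the intersection of
their node sets; nodes isolated by the restriction are retained so every
layer lives on one identical, sorted gene set.

## Preprocessing

Expression intensities are quantile normalized (average-ties dialect),
duplicate gene rows are averaged on the normalized intensity scale, and the
matrix is log2 transformed — in that fixed order. Non-positive values at
the log2 step are a hard error rather than a silent pseudocount, because
intra-array-normalized intensities are expected to be positive; an explicit
`offset` argument (and CLI flag) exists for datasets that genuinely need
one. Normalization is applied to the whole matrix rather than per
condition; the co-expression layer is then built from the samples of a
single condition (tumor by default), because pooling conditions lets
condition-specific expression shifts masquerade as co-expression between
otherwise unrelated genes.

## Backbone filtering

The co-expression layer is complete and the co-targeting layers are dense,
which defeats community detection, so the dense layers are sparsified with
the **disparity filter**. For an edge carrying a fraction
$p = w/s_i$ of endpoint $i$'s strength at degree $k_i$, the null survival
probability is $(1-p)^{k_i-1}$ (the uniform breakpoint null); an edge is
kept when this p-value falls below $\alpha$ at *at least one* endpoint —
the original OR convention, which preserves each hub's multiscale backbone.
Degree-1 endpoints return p-value 1, so pendant edges survive only on the
strength of their other endpoint. The PPI layer has uniform weights (the
filter is undefined there in any useful sense) and passes through
unfiltered.

$\alpha$ is restricted to $[0.01, 0.5]$ and chosen per layer by three
criteria: low output density; a balanced edge budget across layers
(largest/smallest edge count within a fold factor, default 10, reported
jointly rather than optimized per layer); and significant overlap of the
backbone with a user-supplied gold standard of validated interactions,
tested by a one-sided Fisher exact test over the universe of all unordered
node pairs. The recommendation is the sparsest $\alpha$ whose Fisher
p-value stays below the significance level (default 0.05), ties breaking
toward the smaller $\alpha$; if no grid point qualifies the selection
abstains with a warning instead of guessing. A robustness check re-runs
the entire downstream detection at $\alpha/2$, $\alpha$ and $2\alpha$
(clipped to the admissible range) and reports pairwise NMI and the
fraction of gene pairs classified identically (Rand index).

## Consensus community detection

All supported detection algorithms are stochastic, so a single run is an
unreliable summary. Each layer's partition is the *iterated consensus* over
`n_runs` runs (default 100): the co-assignment frequency matrix of the runs
is thresholded at $\tau$ (entries below $\tau$ zeroed; default 0.5,
majority rule) and re-clustered as a weighted graph, until all runs agree —
the matrix is 0/1 and block diagonal — or `max_iter` (default 20) rounds
pass, in which case the majority partition is returned with a warning flag.
The cross-layer partition applies the same machinery to the co-assignment
matrix of the per-layer *best* (consensus) partitions, weighted equally —
a two-stage design: 100 runs per layer first, then one consensus across the
four layer partitions, not one consensus across all 400 raw runs.

Built-in algorithms are Louvain-style multilevel modularity optimization
and label propagation (both respecting edge weights, both randomized
through the R RNG). Other algorithms attach through a registry: any
`function(graph, seed) -> membership` can be registered, and
`external_algorithm_adapter()` wraps binaries under an edge-list-in /
membership-out subprocess contract. Overlapping covers (as produced by
OSLOM-style methods) are reduced to crisp partitions by assigning each
multiply-assigned node to its largest containing module, ties to the
lexicographically smallest module id, homeless nodes to singletons — the
consensus machinery and NMI used here are crisp.

Every stochastic stage draws its per-run seeds deterministically from a
master seed, so complete runs are reproducible; the pipeline writes a
manifest with MD5 checksums of all outputs, and two runs with identical
inputs and seed produce byte-identical manifests.

## Partition comparison

Partition agreement is measured by normalized mutual information with the
arithmetic-mean normalizer, $\mathrm{NMI} = I(A;B) / \frac{H(A)+H(B)}{2}$,
the variant common in the community detection comparison literature; `min`,
`max`, `sqrt` and `joint` normalizers are available behind an argument. The
degenerate case of two one-block partitions is defined as 1; a single-block
partition against anything else scores 0. The robustness check additionally
reports the Rand index (pairwise co-assignment agreement).

## Scoring communities

* **Functional homogeneity.** Every (community, gene set) pair is tested by
  the upper-tail hypergeometric distribution over the multi-network node
  set — not the genome — because communities are drawn from that universe.
  The whole family is adjusted jointly by Benjamini–Hochberg, and a
  community is *functionally homogeneous* when any set is enriched at
  adjusted p < 0.05. The joint family is a deliberate choice: adjusting per
  community (or per collection) produces smaller families and more lenient
  thresholds, and the package prefers one conservative, easily stated
  family over several ad hoc ones. The same joint-family rule governs the
  signature-intersection report.
* **Differential expression.** Per-gene log2 fold change is mean tumor
  minus mean normal log2 expression. A community is summarized by
  (c1) the absolute mean of its genes' fold changes, (c2) a two-sample
  Student's t-test p-value, and (c3) the sample (n−1) standard deviation of
  the fold changes. For c2 the test population is the community's *genes*:
  per-gene mean tumor values against per-gene mean normal values. This
  reading makes all three criteria gene-level summaries of the same
  quantity; it is weak when baseline expression varies strongly across the
  community's genes (the shared baseline inflates both groups' variance),
  and the alternative — per-sample community mean expression, samples as
  units — is available via `genes_as_units = FALSE`.
* **Tumor-specific categories.** With enrichment tables for the tumor and
  normal multi-networks (TM, NM) and tumor and normal expression networks
  (TE, NE), the multi-network's added value is
  $(\mathrm{sig(TM)}\setminus\mathrm{sig(NM)})\setminus
   (\mathrm{sig(TE)}\setminus\mathrm{sig(NE)})$, split by category tag
  (chromosomal location, pathway, TF/miRNA motif, GO). A radar-style export
  lists reciprocal p-values for categories whose best raw p-value is below
  1e−5; the raw-p cut applies only to this export, never to the
  significance calls themselves.

# The synthetic generator

`planted_design()` plants one block structure through all five inputs:
expression follows a factor model with within-block correlation
`rho_within` (default 0.9) on the log2 scale, exponentiated to intensities
so preprocessing applies end to end; regulators target their home block
with `reg_p_in` = 0.3 against `reg_p_out` = 0.01 (20 regulators per block);
the PPI is an SBM at 0.15 / 0.005; the gold standard samples 500
within-block and 50 between-block pairs; tumor samples add per-gene shifts
drawn once from $N(\mu_b, 0.2^2)$ with block means (1, −1, 0.5, 0). The
default scale — 400 genes in four equal blocks, 50 + 50 samples — keeps a
complete end-to-end run in the tens of seconds while leaving the MI, filter
and consensus stages statistically non-trivial; the acceptance checks run
the full pipeline at exactly this scale (with 25–50 consensus runs per
layer, since the consensus already converges in one or two rounds there)
and the heavier simulation-contrast checks use 100-node SBMs over 20
seeds.

What the generator does *not* emulate: microarray noise models
(probe-level effects, background, saturation), heavy-tailed expression
marginals, overlapping or nested communities, hub-dominated scale-free
topologies in the regulatory layers, and incomplete or biased gold
standards. Passing recovery checks on these fixtures therefore
demonstrates that the machinery is implemented correctly and is stable
under its own stated conditions — not that real tumor datasets will yield
communities of comparable purity.

A note on the filter at this scale: with equal-frequency binning at 50
samples the plug-in MI bias puts between-block MI around a third of the
within-block value, so on the complete 400-node graph the within-block
backbone separates only in a window of the $\alpha$ grid (in practice near
0.25) — which is precisely the behaviour the gold-standard criterion is
designed to detect, and why filtered layers keep their MI weights: even a
barely filtered layer remains informative to weighted modularity.

# Numerical choices and degenerate inputs

* Quantile-normalization rank ties are averaged (the common dialect);
  normalization of a single-column matrix is the identity with a warning.
* A constant expression vector occupies a single bin, so its MI with
  anything is 0 by convention; MI values are floored at machine epsilon in
  the co-expression layer so the graph stays formally complete with
  positive weights.
* `disparity_pvalue` validates `weight <= strength` up to a 1e−12 relative
  tolerance; the consensus convergence test treats entries within 1e−9 of
  0/1 as binary.
* Consensus on an edgeless graph yields singletons; clipping that
  collapses the robustness grid to a single $\alpha$ reports trivial
  overlap 1 with a warning.
* BH adjustment rejects p-values outside (0, 1]; enrichment rejects
  communities or sets outside the declared universe rather than silently
  intersecting.

# Known limitations

* Crisp partitions only; overlapping covers are reduced, losing overlap
  information.
* The co-expression estimator is a fixed-bin plug-in; no significance
  threshold is applied before filtering (the complete graph goes in, as
  the workflow prescribes).
* Cross-layer consensus weights layers equally; there is no per-layer
  reliability weighting.
* The Fisher universe is all node pairs of the multi-network, which
  ignores degree structure in the gold standard.
* Infomap, OSLOM and simulated-annealing modularity are supported only
  through the external adapter contract, not bundled.
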