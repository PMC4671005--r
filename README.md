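# genemux

Gene communities from multi-layer interaction networks.

Single-network analyses — a co-expression network alone, or a PPI network
alone — miss regulatory patterns that only show up when several layers of
evidence agree. genemux builds a four-layer **multi-network** over one
shared gene set:

1. **co-expression** — pairwise mutual information (bits, equal-frequency
   binning) between log2 expression profiles, a complete weighted graph;
2. **TF co-targeting** — genes linked by shared transcription factors,
   weight = number of shared TFs (the off-diagonal of the bipartite
   A<sup>T</sup>A);
3. **miRNA co-targeting** — the same projection after keeping only
   interactions supported by ≥ 2 source databases;
4. **PPI** — validated protein-protein interactions, unit weights.

The dense layers are sparsified with the **disparity filter** — an edge
with normalized weight *p* at a degree-*k* endpoint has p-value
(1 − *p*)<sup>*k*−1</sup>, and survives when significant at either endpoint
— with the significance level α ∈ [0.01, 0.5] chosen per layer by output
density, cross-layer edge balance and Fisher-exact enrichment of a
gold-standard interaction set. Communities are then detected by **iterated
consensus clustering**: many stochastic runs per layer (Louvain / label
propagation built in, external algorithms pluggable), a co-assignment
matrix thresholded at τ = 0.5 and re-clustered until all runs agree, then
one more consensus across the four layer partitions. Communities are scored
by BH-corrected hypergeometric gene-set enrichment, tumor-vs-normal
differential-expression criteria and signature intersection. A planted
block-structured generator simulates every input for end-to-end validation.

Intended users: computational biologists integrating expression with
regulatory and interaction evidence, and anyone needing a tested,
reproducible consensus-clustering / backbone-extraction toolkit in R.

## Worked example

```r
library(genemux)

# plant a 4-block structure through all five inputs (400 genes, 50+50 samples)
design <- planted_design(seed = 1)
sim    <- simulate_expression(design)
regs   <- simulate_regulator_tables(design)
pg     <- simulate_ppi_and_gold(design)

expr  <- preprocess_expression(sim$values)              # QN -> collapse -> log2
tumor <- expr[, names(sim$condition)[sim$condition == "tumor"]]

mn <- intersect_to_multinetwork(list(
  build_expression_layer(tumor),
  co_targeting_projection(regs$tf, name = "tf"),
  co_targeting_projection(mirna_consensus_filter(regs$mirna), name = "mirna"),
  pg$ppi))
mn
#> multi-network: 4 layers on 395 shared genes
#>   expression     77815 edges
#>   tf             24549 edges
#>   mirna          15349 edges
#>   ppi             3181 edges

sel <- select_alpha(mn$expression, pg$gold)
sel$report
#>   alpha edges    density     fisher_p
#> 1  0.01     0 0.00000000 1.000000e+00
#> 2  0.05     0 0.00000000 1.000000e+00
#> 3  0.10     0 0.00000000 1.000000e+00
#> 4  0.25  1134 0.01457303 3.485712e-11
#> 5  0.50 77331 0.99378012 3.466116e-02
sel$recommended
#> [1] 0.25

det <- detect_multinetwork_communities(mn, alpha = sel$recommended,
                                       n_runs = 50, seed = 2)
truth <- as_partition(planted_truth(design)[multinet_nodes(mn)])
nmi(det$partition, truth)
#> [1] 1
```

The α grid shows why selection matters: below 0.25 the complete MI graph
loses every edge, at 0.5 it stays near-complete; 0.25 keeps a sparse
backbone (1.5% density) that is strongly enriched in the gold standard
(Fisher p ≈ 3e−11). The cross-layer consensus partition recovers the four
planted blocks exactly (NMI = 1 against the planted truth).

The same workflow runs from files through `run_pipeline()` /
`pipeline_config()` (expression TSV + condition sidecar, regulator tables,
PPI and gold-standard edge lists, optional GMT gene sets), writing layers,
filter reports, partitions, scoring tables and a checksummed
`manifest.json`; `inst/cli/genemux.R` wraps the same functions as a small
command-line tool (`simulate`, `filter`, `communities`, `run-all`).

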