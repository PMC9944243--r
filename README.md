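# scHGTnet

Cell-type-specific biological network inference from single-cell
multi-omics data with a heterogeneous graph transformer.

## What it does, and for whom

Given single-cell multi-omics measurements — multiple scRNA-seq batches,
CITE-seq (RNA + surface proteins), or paired scRNA/scATAC-seq — scHGTnet
builds one integrated gene-activity matrix $X$ (genes × cells), turns it
into a bipartite **cell–gene heterogeneous graph** (an edge wherever
$x_{ij} > 0$), and learns **joint embeddings of cells and genes** with a
heterogeneous graph transformer (HGT) trained as a graph autoencoder:
the HGT is the encoder, the inner product of embeddings the decoder, and
the loss the KL divergence between column softmaxes of the reconstruction
and the input. Because every edge carries a learned multi-head attention
weight, the model yields a **gene-to-cell importance score**
$a_{ij} = \sqrt{\sum_h \mathrm{ATT}^h(i,j)^2}$ alongside the embeddings.

Downstream, the package

* clusters cells (Louvain on the final cell embeddings, SNN graph,
  resolution 0.4),
* extracts **cell-cluster-active gene association networks** by solving a
  Steiner forest problem per cluster over a graph whose gene–cell edges
  are high-attention links and whose gene–gene edges are high-correlation
  links between gene embeddings (shortest-path 2-approximation),
* and, for paired RNA+ATAC data, assembles **regulons**: TF binding
  affinities over peaks (JASPAR $-\log_{10}p \times 100$ convention,
  sites ≥ 500) combine with peak-to-gene regulatory potential
  ($2^{-d/d_0}$ decay, $d_0 = 10$ kb, truncation at 150 kb, exon special
  case) into regulatory-intensity scores
  $s_{ij|q} = \sum_k b^A_{qk} w_{ik} x^A_{kj}$, regulon activity scores,
  **cell-type-specific regulon** calls (one-vs-rest Wilcoxon, BH < 0.05,
  log2FC > 0.10) and master-TF ranking by eigenvector centrality.

It is aimed at computational biologists who want an end-to-end,
dependency-light, fully scriptable implementation of this modeling
approach in R, with a built-in synthetic multi-omics simulator so every
stage is testable without external downloads. The evaluation-metric suite
(ARI, silhouette, Calinski–Harabasz, Davies–Bouldin, closeness and
eigenvector centrality) ships with the package and is validated against
brute-force oracles.

## A worked example

```r
library(scHGTnet)

fix <- make_rna(fixture_spec(seed = 1))   # 300 cells x 500 genes, 3 planted clusters
cfg <- pipeline_config("multi_rna", seed = 2)
run <- run_pipeline(list(rna_list = list(fix$counts)), cfg)

print(run$labels)
#> <cluster_labeling> 300 cells in 3 clusters (resolution 0.4)
#> cluster
#>   1   2   3
#> 101 101  98

ari(run$labels$assignment, fix$truth$cell_labels)
#> [1] 0.9800173

summary(run$fit)
#> HGT graph autoencoder fit
#> <hgt_gae> 2-layer, 16-head HGT graph autoencoder
#>   500 genes x 300 cells, d = 112
#>   final loss 0.1424 after 3008 iterations
#>   attention scores on 73250 edges: mean 0.01903, sd 0.02076
```

The three planted populations are recovered essentially one-to-one: an
adjusted Rand index of 0.98 corresponds to a handful of misassigned
boundary cells out of 300 (1 would be a perfect match). `plot(run$fit)`
draws the GAE training-loss trace; `run$networks` holds the per-cluster
gene association networks; on paired RNA+ATAC input, `run$ctsr` is the
cell-type-specific regulon table.

A thin command-line front end is included for shell use:

```sh
Rscript inst/cli/schgtnet.R simulate --type rna_atac --out fixture_dir --seed 1
Rscript inst/cli/schgtnet.R run --type rna_atac --in fixture_dir --out results_dir
```

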