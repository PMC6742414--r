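# hullclust

Iterative convex-hull density clustering for single-cell RNA-seq expression
matrices, built to detect major and rare cell types in the same run without
per-dataset parameter tuning.

## The method

Single-cell clustering methods struggle when cell types have very different
densities in expression space, and rare subpopulations (a few cells in
hundreds) carry so little variance that a one-shot PCA embedding hides them
inside major clusters. `hullclust` combines:

* **Convex-hull density clustering.** In a 3-PC embedding, cells are ranked
  by the number of neighbours within a radius R_c derived from the
  pairwise-distance histogram (R_c = (d_max − d_min)/B_c, B_c = 20). The
  densest cell seeds a group from the first bin of its distance histogram
  and the group's convex hull is built. Walking down the density ranking,
  a cell joins the nearest group whose hull it approaches — distance to the
  nearest hull vertex below that hull's mean vertex–vertex distance
  (R_P^H < R̄_H) — expanding the hull; otherwise it is a new local density
  maximum and seeds its own group. Remaining cells take the label of the
  nearest peak. The seeding bin size B_g is chosen by scanning 5, 10, …, 100
  until the local-maximum count saturates.
* **An iterative outer loop.** Clusters are scored by the variance σ² of
  within-cluster correlation distances x_ij = 1 − cor(v_i, v_j) on the
  current variable genes. While a Gini index over the cluster variances,
  Gini = ΣΣ|σ_i² − σ_j²| / (2 n² μ), exceeds 0.05 on some top-i prefix, only
  the tightest ("mature") cluster is frozen and removed; variable genes
  (binned dispersion z-score > 1.5, mean ≥ 0.5) and the 3-PC embedding are
  recomputed on the remainder. Structure hidden under dominant clusters
  becomes separable as they are peeled away — which is what recovers rare
  types. Finally, clusters whose centroids correlate above 0.8 (correlation
  distance < 0.20) are merged on an average-linkage dendrogram.

The package also ships the benchmark machinery: Gaussian-blob generators
(500 cells × 20,000 genes; 3–22 centres; SD 0.5/1/2; values rescaled to
0–10,000), the rare-cell variant (one random cluster down-sampled to 10%),
sweep enumerators (1,200 main / 260 rare configurations), an Adjusted Rand
Index, and the rare-cell recovery / false-positive scoring rules.

## Worked example

```r
library(hullclust)

# a rare-cell benchmark dataset: 10 clusters of 50 cells, one down-sampled
# to 5 cells (ground-truth "rare" type), 500 x 20,000 rescaled to 0..10,000
data <- generate_rare(rare_config(n_centers = 10, seed = 7))
sum(data$labels == data$rare_label)
#> [1] 5

part <- hullclust(data$matrix)      # ~5 s on one core
part
#> cell_partition: 455 cells in 10 clusters

adjusted_rand_index(data$labels, partition_labels(part))
#> [1] 1

out <- rare_outcome(data$labels, data$rare_label, partition_labels(part))
out$recovered; out$false_positive
#> [1] TRUE
#> [1] FALSE
```

The partition is exact: all nine 50-cell clusters are reproduced and the
5-cell rare subpopulation comes back as its own cluster with exactly the
right cells (`recovered` demands strict set equality). `part$trace` shows
the 11 iterations the search took: each one freezes the tightest cluster
and re-embeds the remainder, and the run stops when the remaining clusters
are equally tight (all prefix Gini ≤ 0.05).

A thin command-line wrapper is installed at `inst/cli/hullclust`
(subcommands `run`, `simulate`, `benchmark-rare`, `benchmark-main`; flags
mirror the eight method parameters with their defaults).

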