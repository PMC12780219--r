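# scgain

Rare marker-defined cell populations — on the order of 0.1% of a tumor
specimen — are invisible to standard single-cell RNA-seq clustering: a
handful of double-positive cells contributes nothing to the principal
components that drive a kNN graph, and community detection dissolves them
into the surrounding clusters. `scgain` implements **input-gain
clustering**: the log-normalized expression of chosen marker genes (e.g.
*SLC52A2* and *NOTCH1*, which mark a dormant, stably therapy-resistant
lung-cancer population) is multiplied by a constant gain $g$ (default 5)
upstream of feature selection and PCA, so the marker axes dominate the
leading components and the rare population becomes a separable cluster.

The core step: with log-normalized expression $x_{cg}$ and marker set $M$,

$$ \tilde x_{cg} = \begin{cases} g \, x_{cg} & g \in M \\ x_{cg} & \text{otherwise} \end{cases} $$

followed by HVG selection with $M$ forced in, z-scoring in which marker
columns are standardized and clipped on their pre-gain scale (so the scaled
marker column is exactly $g$ times the unmodified pipeline's column), PCA,
a shared-nearest-neighbour graph, and Leiden clustering. At $g = 1$ the
pipeline is bit-identical to the standard one.

Around this core the package provides the full workflow: QC filtering
(≥ 200 detected genes, ≤ 5% mitochondrial counts), log-normalization, a
position-smoothed expression CNV score $S_c = \tfrac1G \sum_g m_{cg}^2$
with a strict positivity gate ($S_c > 1.009$) restricting the analysis to
tumor cells, marker-threshold cell selection and recovery metrics,
Wilcoxon / negative-binomial Wald differential expression with
Benjamini–Hochberg correction, preranked GSEA (classic weighted
running-sum statistic with a gene-set permutation null) and hypergeometric
gene-set overlap, plus a seeded negative-binomial simulator that plants a
ground-truth rare population so everything is testable against known
labels.

## Worked example

```r
library(scgain)

run <- run_full(pipeline_config(seed = 1))
glance(run)
```

```
# A tibble: 1 × 12
  n_cells n_cells_qc n_cnv_positive marker_cluster cluster_size recovery_fraction
    <int>      <int>          <int>          <int>        <int>             <dbl>
1   20000      19385          15313             11           20             0.952
  precision_vs_threshold population_fraction recall_truth precision_truth n_deg
                   <dbl>               <dbl>        <dbl>           <dbl> <int>
1                      1             0.00131            1               1     6
```

Reading the row: of 20,000 simulated cells (20 of them planted
double-marker cells), 19,385 pass QC, 15,313 non-reference cells pass the
CNV gate, and with gain 5 the clustering isolates a 20-cell marker cluster
— all 20 planted cells at precision 1.0, 95.2% of the threshold-selected
double-positive set, i.e. 0.13% of the analysed cells, matching the
planted 0.1% regime. The same run's enrichment table recovers the planted
dormancy signature as suppressed in the rare population:

```r
run$gsea[1, c("gene_set", "es", "nes", "p_perm")]
#   gene_set                es   nes    p_perm
# 1 dormancy_signature  -0.859 -2.84   0.00203
```

Rerunning with `gain.gain = 1` leaves the marker cluster unfound — the
contrast the method exists to demonstrate. `plot_embedding(run)`,
`plot_cnv_scores()` and `plot_enrichment()` draw the standard pictures;
`tidy(run)` gives the per-cell table.

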