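# mddsig

Imaging-transcriptomics gene signatures in major depressive disorder
(MDD).

Structural and functional brain changes in MDD — measured per cortical
site as case–control contrasts in grey matter density (GMD) and in three
resting-state functional indices (ALFF, fALFF, ReHo) — can be linked to
gene expression by asking which genes' spatial expression profiles
co-vary with the contrast maps. `mddsig` implements that association
analysis and the downstream characterization of the resulting gene
classes, for researchers working at the interface of transcriptomics
and neuroimaging.

## The method

For gene expression profile $x$ and contrast map $m$ over $n$ sites,
the statistic is Spearman's $\rho(x, m)$; significance comes from a
permutation null (map shuffled across sites, default 10,000
permutations) with the add-one two-sided estimator
$p = (1 + \#\{|\rho_{perm}| \ge |\rho_{obs}|\})/(n_{perm}+1)$. A gene
is *depression-related* when $p < 0.001$ for GMD **and** for at least
one functional index. Selected genes split by directional effect:

* **Class 1** — $\rho_{GMD} < 0$, significant functional $\rho > 0$
  (negative effect for grey matter density);
* **Class 2** — the mirror image.

The classes are then characterized by:

* **Network topology** — degree, betweenness centrality and clustering
  coefficient on the interaction graph thresholded at
  `combined_score > 900`;
* **Temporal–spatial specificity** — the specificity index
  $SPI_i = x_i / \lVert X \rVert_2$ and the dispersion index
  $DPI = \sqrt{\tfrac{n}{n-1}\sum_i (SPI_i - \overline{SPI})^2}$
  (0 = uniform expression, 1 = single-sample concentration) computed on
  per-period and per-region mean profiles of a developmental
  transcriptome (8 periods × 16 regions);
* **Reference overlap and enrichment** — overlap percentages against
  risk-gene and differential-expression lists, and upper-tail
  hypergeometric term enrichment filtered at adjusted p < 0.01,
  count ≥ 3, enrichment factor > 1.5;
* **Sex differences** — per-gene female-vs-male t-tests pooled over the
  periods sampled in both sexes.

A synthetic-data generator (`simulate_study()`) produces every input
with planted ground truth — planted expression–map correlations,
region/period-specific genes, sex-biased genes, hub/periphery network
structure — so the full pipeline is testable without external data.

## Worked example

```r
library(mddsig)

cfg <- study_config(n_genes = 500L, n_sites = 100L, n_class1 = 40L,
                    n_class2 = 50L, n_per_group = 50L, n_nodes = 300L,
                    n_period_specific = 25L)
study <- simulate_study(cfg, seed = 1)

maps    <- difference_maps(study$imaging)          # per-site t, BH-corrected
assoc   <- identify_depression_genes(study$expr, maps, alpha = 0.001,
                                     n_perm = 1000, seed = 1)
classes <- classify_directional(assoc$records, assoc$selected,
                                alpha = 0.001)
table(classes$class)
#>       Class1       Class2 unclassified      control
#>           40           50            0          410
```

All 40 planted Class-1 and 50 planted Class-2 genes are recovered, with
no false positives. Class comparisons on the developmental set and the
interaction network:

```r
class_dpi_comparison(study$dev, classes)$tests
#>       axis        comparison      t        p mean_a mean_b
#> 1 temporal Class1_vs_control -5.121 4.74e-07 0.0229 0.0347
#> 2 temporal Class2_vs_control -5.130 4.29e-07 0.0234 0.0347
#> 3 temporal  Class1_vs_Class2 -0.412 6.81e-01 0.0229 0.0234
#> 4  spatial Class1_vs_control 60.607 2.35e-42 0.1425 0.0347
#> 5  spatial Class2_vs_control 87.580 9.75e-62 0.1464 0.0347
#> 6  spatial  Class1_vs_Class2 -1.837 7.02e-02 0.1425 0.1464

topo <- compute_topology(build_graph(study$edges, 900))
head(compare_topology(topo, classes), 3)
#>   metric        comparison      t        p mean_a mean_b n_a n_b
#> 1 degree  Class1_vs_Class2 -13.16 8.65e-21   1.84   7.00  37  50
#> 2 degree Class1_vs_control -12.05 2.14e-26   1.84   9.44  37 210
#> 3 degree Class2_vs_control  -3.49 5.63e-04   7.00   9.44  50 210
```

The planted structure is read off directly: depression-related genes
show **higher spatial DPI** and **lower temporal DPI** than control
genes (positive spatial t, negative temporal t), and Class-1 genes sit
on the **network periphery** (mean degree 1.84 against 9.44 for
controls).

`run_pipeline(run_config(...), out_dir)` executes all stages in
dependency order and writes every table (contrast maps, classification,
overlap, enrichment, topology, DPI, grids, sex differences) plus a
manifest with checksums; reruns with the same configuration are
bit-identical.

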