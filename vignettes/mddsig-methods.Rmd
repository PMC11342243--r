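---
title: "Methods: imaging-transcriptomics gene signatures and their characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imaging-transcriptomics gene signatures and their characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mddsig)
```

## The analysis in one paragraph

`mddsig` asks which genes' spatial expression profiles track where the
brain differs between patients with major depressive disorder and
controls. The inputs are (i) a gene-by-site expression matrix derived
from brain-wide microarray sampling, and (ii) per-subject, per-site
values of four imaging indices — three functional (ALFF, fALFF, ReHo)
and one structural (grey matter density, GMD). Case–control contrast
maps (per-site t-values) are correlated with each gene's site profile
by Spearman's rank correlation; significance comes from a permutation
null; genes associated with both structure and function are split into
two directional classes; the classes are then characterized by
interaction-network topology, temporal–spatial expression specificity
on a developmental transcriptome, reference-list overlap and term
enrichment, and sex-differential expression.

## Contrast maps

`group_difference_map()` computes a two-sided two-sample t per site,
with the convention that positive t means cases exceed controls. The
default is the pooled-variance Student test, matching conventional
neuroimaging group statistics; a Welch option documents the fact that
nothing in the analysis pins down the variance assumption. Sites where
both groups are exactly constant are degenerate: p is set to 0 when the
means differ and 1 otherwise, and a message reports how many sites were
affected. Multiple-comparison control is Benjamini–Hochberg
(`bh_correct()`, a thin wrapper over `stats::p.adjust`) with a default
threshold of q = 0.001.

Covariate regression (age, sex, acquisition site) is deliberately out
of scope: the package operates on per-site scalars that are assumed to
be already harmonized upstream.

## Association and classification

For gene expression vector $x$ and contrast map $m$ over $n$ sites,
the statistic is Spearman's $\rho(x, m)$ with average ranks for ties.
The null is formed by permuting the map across sites (equivalently,
shuffling site labels) and the two-sided p-value uses the add-one
estimator

$$p = \frac{1 + \#\{|\rho_{perm}| \ge |\rho_{obs}|\}}{n_{perm} + 1},$$

so $p \ge 1/(n_{perm}+1)$ and, at the default 10,000 permutations, the
selection threshold $p < 0.001$ is exactly attainable. The permutation
null does **not** preserve spatial autocorrelation — no spin-test
surrogate maps are used — which reproduces the original analysis
design; users should be aware that spatially smooth maps make this
null anti-conservative on real cortical data. By default one seeded
permutation set is shared across genes within each index, which makes
runs reproducible and lets the gene-by-permutation correlations be
computed as a single rank-matrix product; independent per-gene
permutations are available via `share_permutations = FALSE`.

A gene is *depression-related* when its permutation p is below alpha
for GMD **and** for at least one functional index. Selected genes are
then classified by `classify_directional()`:

* **Class 1** — negative GMD correlation, every *significant*
  functional correlation positive (negative effect for grey matter
  density);
* **Class 2** — the mirror image;
* **unclassified** — significant functional correlations of mixed
  sign. The two-class description is exhaustive only when no mixed
  genes occur; rather than silently forcing them into a class, the
  package surfaces them under their own label.

Only the significant functional correlations constrain the class: a
non-significant functional $\rho$ of "wrong" sign carries no evidence
and is ignored.

## Expression pre-processing

The probe-level pipeline mirrors a standard brain-atlas workflow on
tabular inputs: probes failing to surpass background in strictly more
than half of the sites are dropped (a probe at exactly 50% is kept —
the rule only eliminates majority failures); each gene keeps its
peak-intensity probe (highest mean across sites, ties broken to the
lexicographically smallest probe id for determinism); normalization is
per-gene donor-mean centering, then the scaled robust sigmoid
$1/(1+\exp(-(x - \mathrm{median})/(\mathrm{IQR}/1.35)))$ min–max
rescaled to $[0,1]$, then a per-gene z-score across all supplied sites.
Donor-mean centering is this package's batch-removal step: what the
tests assert is its post-condition — a pure between-donor offset leaves
no correlation with the donor indicator — rather than any particular
external tool. Probe re-annotation and atlas ontology handling are out
of scope; the probe-to-gene map is an input.

## Temporal–spatial specificity: SPI and DPI

For a nonnegative profile $X = (x_1,\dots,x_n)$, the specificity index
of sample $i$ is the cosine of the angle between $X$ and the
axis-embedded single-sample vector $X_i = (0,\dots,x_i,\dots,0)$:

$$SPI_i = \frac{x_i}{\lVert X \rVert_2}, \qquad \sum_i SPI_i^2 = 1 .$$

The dispersion index summarizes the SPI profile:

$$DPI = \sqrt{\frac{n}{n-1} \sum_{i=1}^{n} (SPI_i - \overline{SPI})^2},$$

which is 0 for uniform profiles, exactly 1 for single-sample deltas,
bounded in $[0,1]$, and invariant to positive scaling — so it compares
across expression levels and profile lengths. SPI is computed on raw
nonnegative expression, never on z-scores: cosine specificity is
meaningless on signed data, and the input contract enforces
nonnegativity.

```{r dpi-examples}
dpi(c(1, 1, 1, 1))   # uniform
dpi(c(1, 0, 0, 0))   # single-sample concentration
dpi(c(3, 4))         # hand-checkable intermediate value
```

Temporal and spatial profiles are per-axis **means over samples**: the
temporal profile is the length-8 vector of per-period means, the
spatial profile the length-16 vector of per-region means. The phrase
"expression of samples in a period as a profile" is ambiguous between
per-sample and per-level profiles; per-level means are the only reading
under which DPI is genuinely unaffected by unbalanced sampling, so that
is the implemented one. `class_dpi_comparison()` contrasts classes with
two-sided t-tests per axis; `overexpression_grid()` computes, per
(period, region) cell, a t-test of class-gene versus control-gene mean
expression. The grid threshold defaults to 0.01, with the stricter
0.001 available as an argument — both values are quoted in different
places by the analysis this package follows, so neither is presumed and
the choice is exposed.

## Network topology

`build_graph()` keeps interaction edges with confidence
`combined_score` strictly above 900 (0–1000 scale), drops self-loops
and collapses duplicates keeping the maximum score. Metrics are degree,
unnormalized betweenness centrality over unordered pairs, and the local
clustering coefficient (0 for degree < 2); they are computed with
igraph and verified in the test suite against a hand-written exhaustive
shortest-path oracle on all random graphs up to 8 nodes. Genes absent
from the thresholded graph are excluded from class comparisons by
default — interaction coverage is partial, and zero-filling would
manufacture a group difference; `include_missing_as_zero = TRUE`
implements the other convention since the source analysis does not
state which was used.

## Reference lists and enrichment

Differential expression on case–control expression tables is a
per-gene two-sided t-test (default retention p < 0.01, direction
"down" when the case mean is lower). Overlap of a class with a
reference list is $100 \cdot |class \cap ref| / |class|$, reported
together with the raw counts, because percentages over small
numerators are fragile on their own. Term enrichment uses the
upper-tail hypergeometric probability, BH adjustment across terms, and
the filter: adjusted p < 0.01, overlap count ≥ 3, enrichment factor
(observed/expected overlap fraction) > 1.5. "Multi-test adjustment" is
interpreted as BH for consistency with every other correction in the
pipeline.

## Sex differences

`sex_de_genes()` restricts to the periods sampled in both sexes and
pools across them into one two-sided t-test per gene (a single
p-value per gene implies a pooled test; the restriction prevents
period-composition confounding when one sex is missing from a
period). `sex_bias_percentages()` tabulates, per class, the share of
sex-different genes higher in females versus males.
`sex_overexpression_grid()` contrasts per-gene female-minus-male
differences of the sex-different genes against those of control genes
within each (period, region) cell — differencing removes shared
regional baselines; the class-vs-control reading of the grid follows
the source analysis' caption, and the per-gene-difference contrast is
the implementable form of it.

## The synthetic-data generator

The generator produces every pipeline input with planted ground truth.
Its defaults are the study conditions the tests and the recovery suite
run under, chosen once at design time:

* **Imaging**: 200 sites, 100 subjects per group, unit noise. The four
  effect maps share one latent spatial pattern $s$; functional indices
  shift cases by $+0.5\,s$, GMD by $-0.5\,s$, plus per-index jitter
  (SD 0.05). The shared latent is what makes a single gene profile
  correlate with all four maps simultaneously, with opposite signs for
  structure and function — the phenomenon the selection rule targets.
* **Expression**: 2,000 genes with 150 Class-1 and 200 Class-2 planted
  genes (echoing the real proportions of ~15,700 genes and a 146/199
  split). A planted profile mixes a Gaussianized rank transform of the
  combined map with weight 0.8; the monotone transform controls the
  Spearman sign and magnitude without assuming linearity.
* **Development**: 8 periods × 16 regions × 4 samples per cell
  (512 samples, near the real 547), Gaussian noise (SD 1) around
  baseline 5 clamped at 0, region/period shifts of 3, sex shifts of 1.
  Every class gene is region-specific; 100 control genes are planted
  period-specific, emulating the developmentally regulated genes that
  exist in any real control population and give it temporal
  dispersion. Without them, control genes would be implausibly flat in
  time.
* **Network**: weighted configuration-model sampling; Class-1 nodes
  carry weight 0.3 (periphery), hubs weight 6; retained edges are
  scored in (900, 1000] and decoy edges at or below 900 exercise the
  threshold.
* **Reference lists**: per-group inclusion rates (0.20, 0.10, 0.05)
  for Class 1 / Class 2 / control.

What the generator does **not** emulate: spatial autocorrelation of
cortical maps (so the naive permutation null is exactly calibrated
here, while on real data it is not), donor/batch structure of
microarray expression, LD structure of risk loci, and realistic
scale-free network topology. Passing recovery tests therefore
demonstrates correctness of the pipeline's logic under its own
statistical model, not robustness to those real-data complications.

The control-gene count is a parameter rather than a fixed number: how
the original analysis chose its 4,089 control genes from ~15,700
processed genes is unstated, so the generator treats everything
unplanted as control by default.

## Numerical and design choices

* Permutation counts compare $|\rho_{perm}| \ge |\rho_{obs}|$ with a
  $10^{-12}$ slack so exact ties (e.g. the order-reversing permutation
  of a monotone pair) are never lost to floating-point noise.
* Constant gene rows or maps make rank correlation undefined: scalar
  operations warn and return `NA`; the matrix path flags the rows and
  never selects them; a constant contrast map is an error.
* All randomness flows from explicit integer seeds;
  `simulate_study()` derives fixed per-stage substreams from the root
  seed so stages are independently reproducible.
* Problem sizes in the test suite are desk-scale by design (e.g. the
  recovery suite uses 10 seeds × 2,000 genes × 200 sites × 1,000
  permutations; the brute-force topology oracle 200 graphs of ≤ 8
  nodes); they are the package's own choice of a minutes-scale
  configuration with comfortable statistical power.
* Re-normalizing an already normalized matrix preserves the mean-0 /
  SD-1 invariants and each row's rank order, but not the exact values:
  the sigmoid is nonlinear, and idempotence holds only at the level of
  those invariants.

## Known limitations

* The permutation null ignores spatial autocorrelation (by design, for
  fidelity to the analysis it implements); on real cortical maps a
  spin-test-style null is the defensible choice.
* No covariate adjustment of imaging contrasts.
* The pipeline starts from per-site scalars and a supplied
  probe-to-gene map; imaging preprocessing, sample-to-cortex mapping
  and probe re-annotation are out of scope.
* Classification thresholds interact: at $n_{perm}$ permutations the
  smallest attainable p is $1/(n_{perm}+1)$, so alpha below that makes
  selection impossible — `run_config()` defaults keep the two
  consistent (10,000 and 0.001).
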