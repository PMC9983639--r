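---
title: "Methods: cell-type enrichment and expression strictness"
author: "strictscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-type enrichment and expression strictness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strictscreen)
```

## What the package computes

Given an annotated single-cell expression dataset and a disease gene panel,
`strictscreen` answers two complementary questions.

**Where is the panel's expression concentrated?** The specificity of gene $g$
in cell type $t$ is

$$\mathrm{spec}_{g,t} = \frac{\bar{E}_{g,t}}{\sum_{t'} \bar{E}_{g,t'}},$$

where $\bar{E}_{g,t}$ is the gene's mean expression over the cells of type
$t$. Rows sum to one, so specificity is the share of the gene's expression
budget spent in each type, independent of overall expression level. The
enrichment statistic for a panel in type $t$ is the summed specificity of its
genes, and its null distribution comes from 10,000 random gene lists of the
same size drawn without replacement from all usable genes. The upper-tail
bootstrap p-value uses the standard pseudo-count correction
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(n_\text{boot} + 1)$, with ties
counted toward the tail (conservative), and is Benjamini–Hochberg adjusted
across the cell types of one dataset × panel.

**How tightly is each gene's dosage controlled?** For a gene with per-cell
expression $E_i$ and reference mean $\bar{E}$, the per-cell fold change is
$C_i = E_i/\bar{E}$ and strictness is the inverse sample standard deviation

$$S = \left(\sqrt{\tfrac{1}{n-1}\sum_i (C_i - \bar{C})^2}\right)^{-1}.$$

A dosage-sensitive gene is expressed in a narrow band around its mean, so its
fold changes cluster near 1 and $S$ is large; a gene tolerant to dosage
alterations has dispersed fold changes and small $S$. Because $C_i$ divides
out the gene's scale, $S$ is invariant to multiplying a gene's expression by
any positive constant — the package asserts this to machine precision.

To test whether a panel's *mean* strictness $x$ in a population is high, the
null is built by resampling: 10,000 random same-size gene sets are drawn from
all usable genes, and each set's mean strictness is recorded. By the Central
Limit Theorem these means are approximately normal; their maximum-likelihood
normal fit ($\hat\mu$ the sample mean, $\hat\sigma$ the SD with the $1/N$
denominator, as MLE prescribes) gives
$p = 1 - \Phi\!\left((x - \hat\mu)/\hat\sigma\right)$, one-sided upper tail
only: the scientific claim is "stricter than random", and low strictness is
not evidence of the same kind. Within one screen, p-values are
Bonferroni-multiplied by the number of populations tested.

Per-dataset results for the same (cell type, panel) pair are combined with
unweighted Stouffer's method, $z_k = \Phi^{-1}(1 - p_k)$,
$z_c = \sum z_k/\sqrt{k}$, which is the standard choice for one-sided,
direction-consistent p-values; Fisher's product method is available behind a
flag. The combined p is Bonferroni-corrected over the *pooled* cell-type count
(the sum of each dataset's number of types), a deliberately stringent family:
FDR runs within datasets at the screening stage, Bonferroni once at the
replication stage.

## Reference scope for fold changes

The fold-change denominator and the population over which the SD is taken
need not coincide, and the distinction matters. The default scope,
`"global-ref"`, divides by the gene's mean over *all* cells of the dataset
while the SD is computed over the queried population. Under this scope a
marker gene sitting far above its global mean in its own cell type shows
large fold changes there and is scored lax, which is the behaviour we want
when asking whether disease genes are dosage-controlled *in the cell type
where they act*. The alternative, `"within-type"`, divides by the
population's own mean, making strictness a purely within-population
dispersion measure. Both are implemented; the scope is recorded in every
output row. Genes with a zero reference mean cannot be fold-changed and are
excluded; genes with zero fold-change variance (degenerate, $S \to \infty$)
are excluded from target and null universes symmetrically so that a handful
of infinite values cannot dominate set means.

## The synthetic-data generator

Real datasets of this kind span roughly 5–75 annotated cell types with
overdispersed counts and depth variation across cells; the generator emulates
exactly that structure and nothing more. Counts are negative binomial —
Poisson would leave no room for a "tolerant" gene to be overdispersed — with
mean

$$\mu_{g,c} = m_0 \cdot f^{[g \text{ marks the type of } c]} \cdot d_c,$$

where $m_0$ is `baseline_mean`, $f$ is `marker_fold`, and $d_c$ is a
log-normal per-cell depth factor with unit mean and log-scale SD
`depth_variation`. Each gene carries an NB size $\theta_g$ (variance
$\mu + \mu^2/\theta$) determined by its class: *strict* genes get a large
$\theta$ (tight), *tolerant* genes a small one, and everything else a
background value, so the per-gene dispersion coefficient is
$\alpha_g = 1/\theta_g$. Markers are drawn from the background class only,
keeping the enrichment and strictness ground truths orthogonal. Passing a
previous run's `truth` to `simulate_cells()` reuses the gene classes and
marker map with fresh noise — a replication cohort.

Default conditions (chosen once, as a realistic mid-scale dataset): 10 cell
types × 200 cells, 2,000 genes, 25 markers per type at fold 4, baseline mean
5 counts, $\theta$ = 50 / 1 / 10 for strict / tolerant / background (a 50×
dispersion ratio between the named classes), 100 strict and 100 tolerant
genes, depth SD 0.3. A null dataset is the same generator with
`marker_fold = 1`, no markers, a single $\theta$, and `depth_variation = 0`.
The choice of baseline mean matters: at very low counts Poisson sampling
noise ($1/\mu$) swamps the $1/\theta$ term in the fold-change variance and no
statistic could separate the classes; 5 counts per gene per cell keeps the
dispersion signal visible while staying in a plausible UMI-ish range.

What the generator does **not** emulate: real tissue composition, batch
effects, zero inflation beyond NB sparsity, gene–gene correlation, or
cross-species symbol differences. Tests passing on this generator therefore
show that the statistics recover the structure they are defined on — not that
any particular biological claim about real tissue holds.

## Normalization

Raw counts are CPM-normalized per cell by default before either statistic.
The rationale is mechanical: depth variation is multiplicative on every gene
of a cell, so it inflates fold-change SDs (deflating strictness) without
carrying biological signal, and CPM removes it. The simulator's log-normal
depth factors make this an explicit test: with `depth_variation = 0.3` the
null strictness p-values are uniform only after normalization. A
`normalize = FALSE` switch preserves input values for parity experiments with
pre-normalized matrices (CPM is idempotent on already-normalized cells).

## Numerical choices

* Bootstrap tail counting uses a relative epsilon (`1e-9`) on the `>=`
  comparison so that a null sample that *is* the target set (inevitable when
  the panel approaches the universe) counts as a tie despite
  summation-order round-off.
* The bootstrap p floor is $1/(n_\text{boot}+1)$; p is never 0.
* Strictness degeneracy uses a variance floor of $10^{-12}$; degenerate genes
  report $S = 10^{12}$ with a flag rather than `Inf` so tables stay numeric.
* The null-universe for both tests is all usable genes *including* the target
  genes, matching the cited enrichment method's default.
* `p = 0` or `1` entering the meta-analysis is clamped to
  $[10^{-15}, 1-10^{-15}]$ with a warning rather than rejected: bootstrap
  p-values of exactly 1 are legitimate.
* Sampling is without replacement within each random gene list; lists are
  independent of one another. All RNG flows from a single user-supplied seed,
  and fixed seeds give bit-identical results.

## Accuracy of the CLT approximation

The normal fit to resampled means is an approximation whose error is governed
by the skew of the per-gene strictness distribution divided by
$\sqrt{\text{panel size}}$. On the default simulated dataset the strictness
distribution has skew about $-0.9$ (the tolerant and own-type marker genes
form a long left shoulder), and the measured maximum deviation between the
fitted normal tail and the empirical resampling tail is about 0.01–0.02 for
30–50-gene panels, shrinking to under 0.01 at 300-gene panels (the scale of
loss-of-function-tolerant control panels). Consequently, for small disease
panels the normal p is trustworthy for clear calls but should not be
over-read within ±0.02 of a decision threshold; the
`keep_null = TRUE` option exposes the resampled means so the empirical tail
can be consulted directly in borderline cases.

## Problem sizes used in the validation suite

The test suite validates calibration and power at deliberately moderate
scales: exhaustive enumeration on a 12-gene universe (all 495 subsets of size
4) as the oracle for the bootstrap; 500 random panels on a 1,500-gene null
simulation for type-I uniformity; 100 replicate datasets at the default
conditions for power and ground-truth recovery; and 10,000 resamples for the
CLT fidelity check. These sizes give Monte-Carlo standard errors comfortably
below the tolerances being asserted.

## Known limitations

* Symbol matching across species is case-insensitive equality (human `SOD1` ↔
  mouse `Sod1`); genes whose orthologs are not same-named symbols need an
  explicit two-column ortholog map.
* The strictness test is one-sided by design; "significantly lax" is not
  reported.
* Cell-type label harmonization across datasets is the caller's
  responsibility (an explicit mapping table); there is no fuzzy matching.
* The meta-analysis combines p-values, not effect sizes, and computes no
  heterogeneity statistics.
* With panels of a few dozen genes the CLT p-value carries the ±0.02
  approximation error described above.
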