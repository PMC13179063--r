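---
title: "Methods: brain-wide RABV input mapping analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brain-wide RABV input mapping analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inputmap)
```

## The problem

Glycoprotein-deleted rabies virus (RABV) tracing labels the monosynaptic
inputs to a genetically defined "starter" population — here, cells of the
ventral tegmental area (VTA), in particular its dopamine neurons. Each brain
yields a count of labeled input neurons in each of 22 canonical input
regions. The scientific questions this package addresses are comparative:
do different VTA cell types, or animals exposed to different drugs or
anesthetics, receive systematically different input patterns? And do
regional gene-expression profiles predict where labeling changes occur?

Three properties of these data shape every methodological choice:

1. **Compositionality.** Absolute labeled-cell counts vary over an order of
   magnitude between brains for technical reasons, so each region is
   expressed as a percentage of that brain's total labeled inputs. Rows of
   the fraction matrix sum to 100 by construction.
2. **Small n, moderate p.** Cohorts have 4–24 brains per condition over 22
   regions, so the analysis leans on dimensionality reduction rather than
   region-by-region testing alone.
3. **Injection-site confounding.** The placement of the starter population
   along the medial–lateral (ML) axis of the VTA systematically shifts input
   composition. A key analytical move is to show that this technical
   variance and the treatment effect load on *different* principal
   components.

## The pipeline

### Normalization and PCA

Counts pass a quality filter (brains with fewer than 200 total labeled
inputs are excluded; a total of exactly 200 is retained), become
percentages, and are Z-scored per region. The Z-score uses the population
SD (denominator *n*); the convention is not dictated by the science and is
recorded here so results are exactly reproducible. Constant regions map to
zero rather than NaN so PCA stays defined.

`fit_pca()` is ordinary PCA on the normalized matrix. Component signs are
arbitrary in principle; we fix each component so its largest-magnitude
loading is positive, making loading heatmaps and score plots reproducible
run to run. Loadings are the interpretive core: the regions with large
positive or negative weights on a condition-separating component are the
candidate circuit substrate of that condition.

### Group statistics

`pc_group_test()` follows the standard recipe for scores on a single
component: an unpaired two-sided pooled-variance t test for two groups, a
one-way ANOVA for more, with pairwise t tests run only when the omnibus
p-value is below 0.05. Tukey's HSD is the default all-pairs correction;
Dunnett contrasts are used when a control group is designated; Šidák and
Holm are available. Dunnett p-values come from randomized multivariate-t
quadrature, so the implementation pins a local RNG seed (restoring the
caller's stream) to keep reruns byte-identical.

`condition_ellipsoid()` summarizes each condition's scatter in a 2D
embedding plane: centered at the condition mean and stretched one standard
deviation (population convention, matching the Z-score choice) along the
principal axes of the condition's own scatter.

### Ensemble embeddings and correlograms

Stochastic nonlinear embeddings (UMAP) capture relationships PCA cannot,
but individual embeddings depend on their seed. `ensemble_embed()`
therefore repeats the embedding 20 times and averages the pairwise 2D
Euclidean distances. The backend is pluggable — any function
`(matrix, n_neighbors, metric, seed) -> n x 2 coordinates` that is
deterministic given its seed. The shipped default wraps `uwot::umap` with
exact k-nearest-neighbor search (cohorts are small) and otherwise uses the
backend's defaults; `n_neighbors` defaults to one third of the cohort size
(minimum 2) for a global view of the data, with `floor()` as the rounding
rule.

Per-repeat embedding scale is arbitrary. We do **not** rescale repeats
before averaging by default — with a common data matrix the scales are
comparable in practice — but `rescale = TRUE` normalizes each repeat's
distance matrix to unit root-mean-square first; the choice is recorded in
the result's parameters for auditability. `correlogram()` orders brains by
agglomerative clustering of the mean-distance matrix rows (Euclidean
distances between rows, average linkage — the construction used by default
in clustered-heatmap tools; the linkage is recorded in the output).

### The scramble null

Apparent cluster separation in embeddings can be an artifact of small-n
geometry. `scramble_null()` calibrates it: each permutation shuffles the
condition labels *and* independently permutes every region column across
brains, destroying both group identity and inter-region correlation, then
recomputes a scalar separation statistic in the PC1–PC2 plane of the
scrambled data. The default statistic is the mean silhouette width of the
labels (a between/within distance ratio is available); the empirical
p-value uses the add-one estimator `(1 + #{null >= obs}) / (1 + n_perm)`.

### Starter-location confound

`starter_center_of_mass()` reduces a per-section starter-cell distribution
to an (AP, ML) center: the count-weighted mean AP coordinate, then the
count-weighted mean ML coordinate within the section(s) nearest that AP
center (ties included). The wording of "center point" admits a mode
reading, so `ap_center = "mode"` is available; the weighted mean is the
default because it varies continuously with the data. ML coordinates are
unsigned distances from the midline — hemisphere signs are stripped on
read. `pc_location_regression()` is ordinary least squares of per-brain PC
scores on the ML center, with the two-sided slope test; a large r² flags a
component as injection-site variance rather than biology.

### Projection portraits

For a group of input regions selected from PCA loadings (top-k by default,
k = 5, ties broken by canonical region order; an explicit region list is
always accepted), `build_portrait()` averages connectivity-atlas projection
density grids in two levels: experiments are averaged within each region
first, then region means are averaged with equal weight. This keeps
heavily sampled regions (ten tracing experiments) from drowning out
sparsely sampled ones (one experiment); the pooled single-level average is
available behind a flag. Grids must share shape and slice; no registration
or resampling is attempted.

### Expression atlas correlation

Regional in-situ expression data arrive as per-experiment records. The
quality filter keeps a gene if any experiment used coronal sections, or if
its replicate experiments agree — mean pairwise Pearson correlation of
regional profiles above 0.5. The "mean pairwise" rule is our resolution of
an ambiguity for genes with more than two experiments (all-pairs and
minimum rules are stricter; the mean matches the two-experiment case
exactly and degrades gracefully).

Each experiment profile is normalized by a robust scaled sigmoid —
`1/(1 + exp(-(x - median)/(IQR/1.35)))`, then min–max to [0, 1] — which is
insensitive to single-region outliers; 1.35 converts the IQR to an SD
equivalent. Zero-IQR profiles are degenerate and are excluded with a log
entry. A gene's atlas profile is the mean of its passing experiments'
normalized profiles.

Condition-induced labeling changes are summarized per region as the
difference and the ratio of mean input percentages (experimental vs
control) on the merged 20-region axis, where the three accumbens
subdivisions collapse into one NAc entry to match atlas region definitions.
`gene_screen()` computes each gene's Spearman correlation with the delta
vector (average ranks for ties; exact permutation p for n ≤ 8, t
approximation otherwise) and reports the top-k positively and negatively
correlated genes — rank-based lists, deliberately without multiplicity
correction, because downstream enrichment consumes fixed-size lists.
`enrich_hypergeom()` tests those lists against user-supplied gene sets
(GMT) with the one-sided hypergeometric tail and Benjamini–Hochberg
adjustment across sets. `class_regression()` pools (region, condition)
points pairing a gene class's mean log-normalized expression
(`log(1+x)` then unit scaling, on the unnormalized atlas profiles) with
labeling ratios and reports Pearson r; the log-unit scale is the default
because class scores average across genes with very different dynamic
ranges.

## The synthetic-data generator

No raw study cohort is distributed with the package, so every stage is
exercised on synthetic data with known planted structure.

`generate_cohort()` draws, for brain *i* in condition *c* with starter ML
coordinate *x*ᵢ uniform over 0.2–1.0 mm:

> πᵢ = softmax(base + effect(c) + gradient · (xᵢ − mid) + ε), ε ~ N(0, σ²)

with counts multinomial at a lognormal total (median ≈ 2000, floored at
200, matching the inclusion filter). Effects act on logits so that
compositionality is automatic and a planted "increase" in one region
implies the correct compensatory decreases elsewhere. The defaults encode
the study conditions the package is designed around: 22 regions, 5 brains
per condition across 8 conditions (6 drug treatments, a fluoxetine control,
and a ketamine/xylazine anesthesia arm), a drug effect raising GPe and
lowering DStr by 0.5 logits, a K/X effect on VP/PO/EAM/PVH/LH/PBN, and an
ML gradient carried by accumbens (lateral) versus VP/PO/LHb/DR (medial)
inputs at ±1.2 logits/mm. The gradient regions are deliberately disjoint
from the drug-effect regions so that the treatment-separating and
injection-site components can dissociate — the central control of the
analysis. Per-region logit noise is σ = 0.15, chosen as a realistic
between-animal variability (≈15% multiplicative variation per region).

`generate_expression_atlas()` plants genes whose regional profiles are
rank-matched to a supplied delta vector by *rank surgery*: starting from
the delta ranks (or their reversal), adjacent-valued position pairs are
swapped until the realized Spearman correlation drops to the target, so
the realized value is exactly computable and recorded in the truth record.
Decoy genes are i.i.d. noise. Replicate experiments share a base profile
plus independent noise scaled so the expected cross-replicate Pearson
correlation equals the configured concordance.

`generate_projection_grids()` builds density grids as sums of isotropic
Gaussian hotspots plus nonnegative-clipped noise, clipped to [0, 1].

**What the generator does not emulate:** spatial autocorrelation between
neighboring regions, heavy-tailed count overdispersion beyond the logit
noise, batch effects across experimenters, hemispheric asymmetries, and
any biophysics of viral spread. Passing recovery tests therefore shows the
*statistical machinery* behaves as designed under the assumed data model,
not that the biological conclusions of any particular study are correct.

## Numerical and design choices

- **Inclusive ≥200 filter**: "fewer than 200 excluded" makes exactly 200 a
  kept boundary case.
- **PCA sign fix** (largest-|loading| positive) makes outputs deterministic;
  published figures are sign-arbitrary.
- **Population SD** in Z-scores and ellipsoid radii; both recorded so every
  numeric output is exactly reproducible.
- **Spearman p-values**: exact enumeration of all rank permutations for
  n ≤ 8; the t approximation above. The screen itself selects by rank, so
  p-values are descriptive there.
- **Degenerate inputs** fail loudly with typed conditions: zero-total
  brains, singleton groups, zero-variance predictors, zero-IQR expression
  profiles, non-symmetric distance matrices.
- **Determinism**: every stochastic step takes an explicit seed; the two
  places where library internals randomize (UMAP optimization, Dunnett
  quadrature) are seeded locally with the caller's RNG stream restored.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run entirely on synthetic data at
sizes chosen to make the property checks sharp but quick: oracle
comparisons on matrices up to 12 × 22 and grids of 16 × 16; calibration of
the omnibus test and scramble null over 500 null cohorts of 30 brains;
planted-effect and gradient-dissociation recovery over 100 seeded cohorts
of 12 brains per condition (planted drug effect ±1.5 logits and gradient
±1.6 logits/mm — chosen in the strong-recovery regime, because near the
weak-effect boundary two failure modes are intrinsic to the design rather
than to the implementation: multinomial sampling noise at study-scale
totals limits single-region detectability, and chance ML imbalance
between small groups rotates the treatment direction into the gradient
component so the planted regions slip out of the separating component's
top loadings); ensemble-embedding recovery over
100 cohorts with 20 embeddings each (60 cohorts in the acceptance script's
stochastic-backend leg, which dominates its runtime); and screen recovery
with 10 planted genes among 4,000 decoys over 100 seeds.

## Known limitations

- The 22-region vocabulary and its Allen-atlas conversion are fixed tables;
  no ontology traversal or atlas registration is performed, and atlas-side
  aggregation is an unweighted mean over the constituent atlas regions.
- The Spearman screen treats regions as exchangeable observations; spatial
  or developmental covariance between regions will inflate its effective
  false-positive rate on real atlases.
- Ratios are undefined where the control mean is zero; such regions are
  dropped from ratio-based analyses and listed explicitly.
- The ensemble-distance average is not a metric embedding; it is a
  visualization and clustering substrate, not a quantity with physical
  units.
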