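---
title: "Models and methods behind spatialTME"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spatialTME}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

spatialTME analyses segmented single-cell tables from imaging mass
cytometry (IMC) of tumour tissue: one row per cell with centroid
coordinates in micrometres and raw mean intensity for each antibody in
the panel. The pipeline covers expression normalisation, graph-based
phenotyping with rule-driven annotation, cell-neighbourhood clustering,
and single-cell spatial association statistics. A synthetic-cohort
simulator with known ground truth backs every stage, so the whole
pipeline is testable without any external download. This vignette
explains the models, the tunable parameters, and the design decisions
that were genuinely open.

## The data model

A cohort is a set of cases (patients), each contributing several
rectangular regions of interest (ROIs) imaged at ~1 um pixel
resolution. Coordinates are continuous micrometres with the origin at
the ROI's top-left corner and y increasing downward (image convention).
ROI geometry is supplied explicitly in a metadata table rather than
inferred from the outermost cells: sparse tissue edges would otherwise
shrink the apparent area and inflate every per-mm^2 density.

Cases carry a preoperative volumetric growth rate (% volume change per
year). A tumour is classified *growing* when that rate is at least
20 %/yr and *static* (including shrinking tumours) otherwise; readers
always recompute this classification from the stored rate, so a stale
label can never disagree with it.

## Normalisation and per-case statistics

Raw mean intensities are normalised per marker to the 99.9th percentile
of the pooled cohort distribution and clipped into [0, 1]:
`norm = min(raw, P99.9) / P99.9`. Two choices here were open:

* **Pooling.** The percentile is computed cohort-wide per marker, not
  per ROI. Per-case averages are only comparable across cases if all
  cells share one scale.
* **Clipping.** Values above the percentile are clipped to 1 rather
  than allowed to exceed it; boundedness is what "scaled between 0 and
  1" means operationally. The percentile itself uses linear
  interpolation between order statistics (type 7), fixed so test
  oracles are exact.

Case-level statistics follow the field's normality-gated convention:
Shapiro-Wilk on each variable at alpha = 0.05; if both pass, a
two-tailed Pearson correlation (or unpaired t-test for group
comparisons), otherwise Spearman (or Mann-Whitney). A simple linear
regression is fitted on the raw pairs regardless of branch. Groups
smaller than three cannot be tested for normality and fall back to the
nonparametric branch with a warning. Densities divide pooled case cell
counts by the summed area of that case's ROIs, so ROIs without cells
still count toward the denominator.

## Phenotyping

Cells are clustered on normalised expression with a k-nearest-neighbour
graph (Euclidean, k = 15, symmetrised by union) and Leiden community
detection with the modularity objective. What practitioners do by
manual annotation is mechanised as a declarative rule table so runs are
reproducible: each rule names a population and marker expectations
(`high`, `low`, `pos`, `neg`, `any`). Expectations are evaluated on
cluster mean profiles:

* `high`/`low`: z-score across cluster means at thresholds +0.5 / -0.3.
  The `low` default is deliberately less extreme: with one strongly
  positive cluster among k clusters, every other cluster's z-score is
  bounded near `-1/sqrt(k-1)` (about -0.41 at k = 7), so a symmetric
  -0.5 cut would make `low` unmatchable exactly where it matters (e.g.
  a CD16-low macrophage signature against a CD16-high one).
* `pos`/`neg`: cluster mean above/at-or-below the across-cluster median,
  with a minimal contrast of 0.02 on the normalised scale required for
  `pos`. Without the margin, clusters tied at background level satisfy
  `pos` through sampling noise of order 1e-3; `neg` is inclusive so
  background clusters that tie at the median count as negative.

A cluster receives the fully matching rule with the most satisfied
expectations (ties by rule order); unmatched clusters become `other`,
and clusters with equal labels are merged. Hierarchical types (myeloid,
neoplastic, lymphoid, vascular, proliferative, other) and granular
populations are two rule tables applied to the same clustering.
Proliferative cells can be sub-clustered with a second Leiden pass and
their own rule table.

There is no canonical Leiden resolution for IMC phenotyping; the
package default is 0.5, at which the simulated six-population cohorts
resolve into population-level communities. Higher resolutions split
abundant populations into many clusters, which dilutes across-cluster
z-scores (every extra background cluster drags the mean toward
background); the resolution, k, and both z thresholds are arguments.

## The synthetic cohort

The simulator generates marked spatial point patterns whose statistical
structure matches what the analysis assumes, with full ground truth:

* **Case metadata**: four static and five growing cases by default;
  static growth rates uniform on [-40, 16] %/yr and growing on
  [28, 267] %/yr — the observed ranges of the two classes — so
  classification is consistent by construction.
* **Spatial processes** per population: homogeneous Poisson (complete
  spatial randomness), Thomas (Poisson parents with
  Gaussian(sigma)-scattered offspring — aggregation), and *linked*
  (each point at a uniformly chosen partner point plus isotropic
  Gaussian displacement — direct cross-type attraction). Out-of-window
  offspring are discarded rather than wrapped, matching bounded tissue;
  intensity calibration therefore undershoots nominal near edges, and
  test tolerances account for it.
* **Expression**: `mean_expr * LogNormal` with the lognormal's
  parameters set so the multiplier has unit mean and a chosen
  coefficient of variation (default 0.5) — non-negative and
  right-skewed like IMC intensities.
* **Growth effects**: per-population linear slopes of intensity in
  cells/mm^2 per %/yr, validated to keep intensities non-negative over
  the simulated growth-rate range. Linearity is the simplest structure
  that makes the density-growth correlation analyses recoverable.
* **Default landscape** (`default_scenario()`): clustered Schwann
  cells, clustered alternatively activated TAMs with slope
  +0.5/mm^2/%yr, CSR classically activated TAMs, T cells linked to
  alt-act TAMs (sigma 10 um), clustered vasculature, and a CSR
  proliferative fraction with slope +0.25. Default geometry is six
  1 x 1 mm ROIs per case.

What the simulator does **not** emulate: marker spillover, acquisition
noise and denoising artefacts, segmentation errors, cell-size
variation, and holes/folds in tissue. Passing tests therefore
demonstrate that the estimators recover the structure they target under
clean generative conditions — not that annotation rules or thresholds
transfer unchanged to any particular real dataset.

## Neighbourhood analysis

Per ROI, cells are joined by Delaunay triangulation and long links are
pruned at the 99th percentile of that ROI's edge lengths. Two details
are deliberate:

* Pruning is **per ROI** because densities (and hence typical link
  lengths) differ across ROIs.
* The percentile is the **empirical order statistic** (type-1
  quantile): an interpolated percentile sits strictly below the longest
  edge and would over-prune very small graphs (a triangle would lose an
  edge).

A cell's neighbourhood is all cells within l = 3 graph steps. Each
neighbourhood is summarised by four feature groups, concretised as
follows: population composition (fractions,
sum 1); shape = convex-hull area plus circularity `4*pi*A/P^2`;
distribution = mean and SD of member distances to the neighbourhood
centroid; proximity = mean internal edge length. Neighbourhoods of
fewer than three cells get hull 0 and circularity 1.

Neighbourhood feature vectors (pooled over ROIs) are z-scored and
clustered with Gaussian mixture models (full covariance, k-means
initialisation). After z-scoring, each column is weighted by its
feature group: composition columns keep weight 1; shape, distribution
and proximity each get total weight 0.5 split across their columns.
This keeps cell-type make-up the primary signal — with equal weights
the five geometric columns dominate the space and the mixture clusters
on density gradients instead of composition. The weights are arguments.

The number of clusters K is selected by stability: for each candidate
K, repeated fits on random 80% subsamples are compared by the mean
pairwise Fowlkes-Mallows index on shared cells, and the most stable K
wins (ties toward smaller K). Each stability fit uses a *single*
k-means start — initialisation variability is exactly what makes a
wrong K visible; a multi-start fit would look stable at every K. The
final model at the selected K is instead the best of five starts by EM
log-likelihood (or, when EM fails on near-degenerate clusters, the
lowest within-SS k-means solution). K = 1 is trivially perfectly stable
and should only be included in the range deliberately. Stability could
equally be measured under repeated initialisation alone; subsampling at
0.8 perturbs both the data and the initialisation and is the package's
choice.

Clusters are annotated by enrichment: FC = population frequency in the
cluster over overall frequency; enriched means FC >= 1. The cluster's
category (tumour-, vasculature- or immune-enriched) is the compartment
with the largest summed enriched FC, and the cluster is proliferative
if any proliferative population reaches FC >= 1. Neighbourhood
proximity (observed/expected inter-label edge counts) uses a
within-ROI label permutation null, which preserves each ROI's graph
and label counts and is robust to degree heterogeneity.

### Recovery experiment conditions

The planted-mosaic experiments (used by the tests and the acceptance
script) tile an ROI into K Voronoi domains and ask the full pipeline to
recover them. Conditions, fixed once: total intensity 2000 cells/mm^2
(a typical segmented-cell density for IMC tissue); domain compositions
with a 0.7 dominant population (one-hot compositions create point-mass
feature clusters EM cannot fit, plus maximally distinct boundary-band
clusters); domain centres rejection-sampled to at least 400 um
separation so every planted domain is large enough to be identifiable;
20 stability repeats over K in 2..6. Boundary cells — whose 3-step
neighbourhoods straddle two domains — are the irreducible error source
in these experiments.

## Spatial association

**Quadrat correlation matrices (QCM).** Cells are binned into 100
um-sided square quadrats (only fully contained quadrats; half-open
membership, so a boundary cell belongs to the higher-index quadrat) and
per-quadrat population counts are correlated pairwise (Pearson),
Benjamini-Hochberg adjusted over all unordered pairs, and gated at
adjusted p < 0.05 with non-significant entries set to zero. "Quadrats
of 100 um^2" is read as 100 um-sided squares; a literal 100 um^2
quadrat (10 um side) would be sub-cellular, and the companion
topographical map is explicitly at the 100 um scale.

**Cross-pair correlation function.** For sender set A and receiver set
B on window W:

$$\hat g(r) = \frac{|W|}{n_A n_B} \sum_{a \in A}
  \frac{\#\{b \in B: d(a,b) \in [r, r+dr)\}}{|{\rm annulus}(a;r,r+dr) \cap W|}$$

with dr = 10 um over r = 0-300 um and the annulus-window intersection
area computed in closed form (exact border correction; toroidal and
uncorrected modes exist for oracle tests). g = 1 under independence.
Confidence bands come from resampling senders and receivers
independently with replacement (200 replicates, percentile 2.5/97.5);
points, rather than quadrats or labels, are the resampling unit — a
design decision, since case-level resampling is impossible at
single-ROI granularity. The association call is
made at the bin containing r = 20 um ([20, 30) under the left-closed
convention): positive when the lower band exceeds 1, negative when the
upper band is below 1. For a linked pair with displacement sigma, the
excess over baseline in that bin scales as `1/n_A` at fixed receiver
density, so sparse senders with abundant linked receivers are the
high-power regime — the package's power experiments use 50 senders
with ~600 linked receivers per mm^2.

**Topographical correlation maps** score each 100 um tile by the
z-value of the observed sender-receiver co-count (n_S x n_R in the
tile) against random permutation of the population labels over all
cells of the ROI. Permuting all labels (not just the pair's) is what
gives the null freedom to move the pair's labels between tiles. This
permutation-z definition is the package's own formulation of a local
association score at a fixed spatial scale.

**Adjacency cell networks** draw a directed edge sender -> receiver
only when the pair is QCM-significant *and* the cross-PCF call is not
"none"; edge weight is g(r=20), and % connections is the share of
retained spatial-graph edges incident to sender-type cells that join
them to receiver-type cells. In the orchestrated pipeline, QCM is
computed per ROI and a pair counts as significant for a case group
when it passes in at least half of that group's ROIs (per-ROI
computation with per-group summarisation); the trivially perfect
self-correlation diagonal is excluded from pair selection there.

## Orchestration, seeds, determinism

`run_pipeline()` executes simulate/load -> quantify -> phenotype ->
neighbourhoods -> spatial from one configuration (R list or YAML) with
a mandatory global seed. Every randomised procedure — simulator,
Leiden, GMM, bootstrap, permutations — consumes a seed derived
deterministically from the global seed and a stage tag, so identical
configurations reproduce byte-identical outputs and stages are
independently reproducible. A manifest records the config hash and
output paths; re-running a completed stage under the same hash is a
no-op.

## Problem sizes

The simulated experiments in the tests and the acceptance script use
cohorts of 9 cases with two 600 x 600 um ROIs each (~6k cells) for
end-to-end runs, 1 x 1 mm single ROIs for calibration and power
experiments (300-2000 points per set, 200 bootstrap replicates, 1000
permutations), and 30 mosaic recovery runs; these sizes give stable
pass/fail behaviour for the statistical properties being checked while
keeping a full run in minutes. The full-scale defaults (six 1 x 1 mm
ROIs per case, ~4000 cells/mm^2) remain the package defaults.

## Known limitations

* Rule-based annotation presumes the panel contains the rule markers;
  rules referencing absent markers are skipped rather than partially
  matched.
* GMM stability selection inherits FMI's bias toward coarse partitions;
  very unbalanced domain sizes can make K-1 (merge) or K+1 (boundary
  split) solutions competitive, which is why recovery is stated as a
  rate over seeds rather than a guarantee.
* The cross-PCF bootstrap treats points as the resampling unit within
  one ROI; it quantifies estimator uncertainty for that ROI, not
  case-level biological variability.
* Densities assume the supplied ROI geometry is fully tissue-covered;
  holes inflate areas and deflate densities.
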