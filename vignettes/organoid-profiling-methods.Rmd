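---
title: "Methods: image-based phenotype profiling of tumour organoids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based phenotype profiling of tumour organoids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

orgprofiler implements a complete analysis path for high-content imaging
of patient-derived tumour organoids: from multi-channel z-stacks to
single-organoid features, viability classification, drug-effect
profiling with mechanism-of-action (MoA) clustering, and a multi-view
latent factor model that links morphology, organoid size, gene
expression, somatic mutations and drug activity, including the
projection of drug-induced phenotypes onto factors learned from
unperturbed organoids. Because the imaging data such screens produce is
typically restricted-access, the package ships a synthetic-data module
that generates every input with the statistical structure the analysis
assumes; all tests and the calibration script run against it.

## Imaging

**Maximum-contrast projection.** A 3D stack (3 channels: DNA, actin,
cell permeability; 16 z-slices, 5 µm apart) is projected to 2D by
retaining, per channel and pixel, the value from the slice with the
strongest local contrast. Contrast is defined as the intensity variance
in a `window × window` neighbourhood (default 3, configurable), the
simplest neighbourhood contrast statistic; neighbourhoods are truncated
at image borders and ties break toward the lowest z so the operation is
fully deterministic. The z-choice is made independently per channel,
which preserves per-stain sharpness when stains focus at different
depths. The projection is verified against a brute-force per-pixel
oracle in the test suite. A caveat worth knowing: a pixel whose whole
neighbourhood is uniform has zero contrast on every slice and falls
back to slice 0 by the tie-break — visible in the interior of large
uniform objects.

**Illumination correction** divides each slice by a per-channel
flatfield gain and renormalizes to preserve the channel mean. When no
reference flatfield is available, a smooth gain surface is estimated
from the stack itself by a local quadratic (loess) trend of the mean
projection. This is a single-stack analogue of prospective shading
correction and removes smooth gradients; it cannot correct
high-frequency sensor artefacts.

**Segmentation** thresholds (Otsu by default) a Gaussian-smoothed
composite of the DNA and actin channels, then splits touching organoids
with a distance-transform watershed whose seed spacing is controlled by
`min_seed_distance`. Objects of 300 pixels or less are removed as
debris (301 is retained); the threshold is the model-free outlier rule
used for organoid-scale objects at 10x magnification. A weakly
supervised CNN refinement of the intensity segmentation is out of
scope here; the intensity model is the implementable core and the
watershed post-processing covers the touching-object cases the CNN
would mop up.

## Features

Per-organoid features are computed with EBImage: shape (area,
perimeter, radius statistics, a convex-hull solidity), image moments
(axes, eccentricity plus the seven Hu invariants on the composite
intensity), per-channel intensity statistics, and per-channel Haralick
textures at pixel offsets 1, 2, 4 and 8. Channel-derived names carry
the channel prefix so whole channels can be masked downstream. The
feature catalogue is reproducible but intentionally not matched
feature-for-feature to any specific historical pipeline; it is the
filtering rules that matter:

1. texture offsets larger than the smallest organoid diameter are
   dropped (operationalized as the 5th percentile of equivalent
   diameters, guarding against outlier objects);
2. features undefined (NA) for any organoid are dropped, so the matrix
   never needs imputation;
3. features with median absolute deviation exactly 0 over the dataset
   are dropped — if more than half of organoids share one value the
   feature is considered ill-defined;
4. remaining features are centred per batch (mean subtraction; batch =
   staining/imaging group). The whole operation is idempotent.

**PCA** uses incremental moment accumulation (sums and cross-products
per row chunk), which reproduces full-batch PCA exactly — unlike SGD
variants — while scaling to datasets that stream through memory. The
default of 25 components follows the observation that additional
components add only marginal variance in organoid screens. Components
carry a deterministic sign convention (largest-magnitude loading
positive).

## Landscape and trajectories

UMAP (min_dist 0.1, 15 neighbours, fixed seed, single-threaded) and
leiden clustering are delegated to uwot and igraph; this package owns
the graph construction (shared-nearest-neighbour graph with Jaccard
weights over the union neighbourhoods) and the parameter contract. The
leiden objective is the constant Potts model, under which the
landscape-scale resolution of 1e-7 merges everything except
well-separated structure — on blobs separated by many standard
deviations the kNN graph decomposes into components that CPM never
merges, while a single Gaussian collapses to very few clusters.

Dose trajectories are principal curves fitted by alternating projection
and per-coordinate smoothing-spline regression along arc length (df =
8; stiffer than generalized cross-validation, which overfits curve
tails, and flexible enough for curved dose paths). Fitting uses a
seeded uniform downsample (5% capped at 10,000, floored at 200 points).
Pseudotime is arc length measured from the curve end with the higher
density of solvent-control observations. Convergence is declared when
the mean point-curve distance changes by less than `tol` times the
embedding diameter. Initialization is the first principal axis: shapes
that are exactly symmetric about their principal axis (a parabola
traversed symmetrically) can fold at initialization — a known
limitation of principal curves generally; dose responses, which move
monotonically away from the control density, do not hit it.

## Viability

The live/dead classifier (LDC) is a 10-tree random forest per organoid
line, trained on raw (pre-filter) features to separate DMSO controls
(live) from bortezomib and SN-38 at their two highest concentrations
(dead), with a stratified 60/40 train-validation split. Channel
ablations mask every feature derived from the withheld stain before
training and inference. Per-organoid dead probabilities are binarized
at 0.5 (the natural cut for an averaged vote) and averaged within
wells; a well's score is its dead fraction, viability its complement.
Cross-line evaluation applies one line's model to the other lines'
validation organoids.

CTG (ATP luminescence) plates are normalized in two steps: a robust
loess surface over (row, col) — degree 1, span 0.75, symmetric family
so single outlier wells do not drag the surface — absorbs edge and
gradient effects, then division by the DMSO median anchors controls at
exactly 1. Treatment effects are absorbed as noise by the robust fit
rather than modelled.

Dose-response curves use a three-parameter Hill model with the top
asymptote fixed at 1 after normalization:
`v(c) = E_inf + (1 − E_inf) / (1 + (c/EC50)^h)`. The fit is
Levenberg–Marquardt least squares over a grid of starting values (every
tested dose as EC50 candidate, slopes 1 and 2), with box constraints
(EC50 within 10^4 of the tested range, slope in [0.05, 10], E_inf in
[0, 1.5]); non-convergence falls back to a flagged trapezoid AUC. The
AUC is the mean of `1 − min(v, 1)` over the tested log10-dose interval,
so 0 means no effect and values near 1 mean complete kill everywhere.
On the 5-point five-fold dilution design with 5% response noise the
AUC is stable (±0.05), while EC50 is only weakly identified from a
single curve — the three parameters trade off, and the least-squares
estimate of EC50 is median-biased low by ~20% when the EC50 sits at
the edge of the tested range. The calibration protocol therefore
evaluates EC50 recovery as the median across the screen's 11 organoid
lines with the EC50 bracketed by the dilution series, which is how
such screens choose their concentration ranges in the first place.

## Drug activity and MoA

A drug-effect profile is the coefficient vector of an L2-regularized
logistic regression separating one drug's organoids from DMSO controls
of the same line in 25-PC space — the normal of the separating
hyperplane, read as the direction of phenotype change. Organoids are
split 50/50; the penalty is chosen on the first half by 5-fold
cross-validated AUROC over 7 log-spaced values (1e-3 to 1e3); the
final model is refit on the second half, whose 10-fold
cross-validation (pooled out-of-fold predictions) yields the reported
AUROC. AUROC is oriented to at least 0.5 with a matching coefficient
sign flip. A drug is *active* when its mean AUROC across lines
strictly exceeds 0.85. Null calibration: effect profiles fitted to
treatment-free data give oriented AUROCs with mean ≈ 0.53 and
essentially never cross the activity threshold. A 2-pooled-SD mean
shift corresponds to a theoretical AUROC of Φ(2/√2) ≈ 0.92, safely
above threshold — but not above 0.95, which a 2-SD shift cannot reach.

For clustering, each drug's vector is the concatenation over lines of
its unit-normalized direction scaled by `(AUROC − 0.5)·2`, so lines
where the drug is more active weigh more; lines without data contribute
zeros. Distance is 1 − cosine similarity with average linkage
(euclidean-on-mean-shift and Pearson modes are provided for
comparison). MoA enrichment walks the dendrogram bottom-up, testing
every node with at least 3 leaves for each target present among its
leaves with a one-sided Fisher's exact test; unannotated drugs count
as non-target, and Benjamini–Hochberg correction runs across all
node × target tests (the correction is a package choice; reported
enrichment conventions vary). The Fisher p-values are verified against
an exact hypergeometric oracle in the tests.

## Multi-view factor model

The five views describing unperturbed lines are: organoid size (the
location of the large component of a two-component log-normal mixture
over DMSO organoid areas, motivated by the characteristic bimodal size
distribution; a single log-normal fallback is flagged if the EM fit
degenerates), binary somatic mutations, expression restricted to the
top 10% of genes by coefficient of variation (ties broken by gene
order), mean DMSO morphology in 25-PC space, and the AUROC activity
matrix restricted to drugs active in at least one sample. Each view is
feature-wise z-scored and scaled to unit total variance; the scaling
state is stored for later projection.

The factor model `Y_v ≈ Z W_vᵀ` (k = 3) is fitted by alternating least
squares with a small ridge penalty; samples missing from a view (e.g.
lines without mutation profiling) are simply excluded from that view's
objective rather than imputed. This estimator deliberately stands in
for variational multi-omics factor analysis: the contract is subspace
and variance-decomposition recovery, not parameter-for-parameter
equality with any specific implementation. After convergence the
solution is rotated to the principal axes of the scores (factors
ordered by explained variance) and each factor's sign is set by
positive correlation with the size view where informative, otherwise
by its largest loading. Variance explained per factor and view is
`100·(1 − SS(Y_v − z_f w_vfᵀ)/SS(Y_v))` with the factor alone.
Rotational ambiguity is the reason all tests compare factors by
matched correlations or subspace angles, never element-wise.

Drug-induced phenotypes are projected through the pseudoinverse of the
transposed morphology loading matrix: `Z_proj = Y·pinv(Wᵀ)`, the
least-squares solution of `Y ≈ Z_proj Wᵀ` and the only dimensionally
consistent reading of a loading-matrix pseudoinverse projection.
Profiles are standardized with the training view's stored scaling
before projection — without this the pseudoinverse is meaningless.
Projecting the model's own morphology rows reproduces the training
scores (exactly at full rank in the noiseless case).

Preranked GSEA uses the weighted running-sum statistic (weight 1) with
a gene-label permutation null: `NES = ES / mean(|ES_null|)` over
same-sign permutations and `p = (1 + #{same-sign |ES_null| ≥ |ES|}) /
(n_same + 1)`. Null p-values are verified uniform and the ES is checked
against a brute-force running-sum oracle. Drug-target association fits
`lm(value ~ is_target)` per target with at least 3 annotated
inhibitors, with BH correction across targets; all-constant inputs are
reported with a zero-variance flag rather than an error.

## Synthetic data: what it emulates, and what it does not

The generator reproduces the statistical structure the analysis relies
on: 384-well layouts with per-plate DMSO and bortezomib/SN-38 controls
(the DMSO well count per plate is unspecified in screen descriptions
and is exposed as a parameter, default 16); line-specific two-component
log-normal size mixtures; cystic (actin ring around a dark lumen) vs
solid rendering; dead organoids as a distinct small, permeability-high,
actin-texture-poor cluster (positive-control wells kill every organoid
by default); per-treatment morphology shift directions shared within
MoA groups, scaled log-linearly across each drug's dilution series —
pharmacological effects are approximately linear in log-dose within a
tested range; and a 22-sample, five-view dataset from a known 3-factor
linear model with paired replicates (jitter sd 0.1 of signal),
decaying factor strengths (1, 0.7, 0.45) mirroring the decreasing
per-factor variance of real factor analyses, and realized factor
scores decorrelated across factors, as the factor-model likelihood
assumes — without distinct strengths and decorrelated scores the
generating factors would be unidentifiable up to rotation and
recovery could not be scored factor-by-factor.

What it does not emulate: optics (a Gaussian PSF and additive noise
stand in for the camera), nucleus-level structure, batch effects beyond
mean shifts, correlated feature noise, and the long-tailed artefact
spectrum of real screens. Passing tests therefore demonstrate that the
algorithms are implemented correctly and calibrated under their own
assumptions — not that those assumptions hold on any particular real
dataset. Headline numbers from real screens (numbers of clusters,
retained features, variance fractions) depend on restricted data and
are not reproduced here.

## Problem sizes and numerical choices

The test and calibration runs use desk-scale sizes chosen to estimate
each quantity stably: 100 random stacks for the projection oracle,
about 1,000 control organoids per line for classifier calibration, 200
organoids per well for death-fraction recovery, 500 organoids per arm
and 50 drugs for null activity calibration, 15 drugs in 3 MoA groups
for clustering, the full 22 × 5-view design for factor recovery, 11
replicate curves for dose-response calibration, and 200 random sets at
1,000 permutations for GSEA null uniformity. Convergence tolerances:
ALS stops at a relative objective change of 1e-12 (ridge 1e-8);
principal curves stop when the mean projection distance changes by
less than 1e-4 of the embedding diameter; mixture fits use a fixed
(first-2000-points) initialization subset so repeated assemblies are
bitwise identical.
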