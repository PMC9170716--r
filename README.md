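# orgprofiler

High-content, image-based phenotype profiling of patient-derived tumour
organoids in R. The package covers the full analysis path of an
organoid drug screen at single-organoid resolution:

- **Imaging** — maximum-contrast projection of multi-channel z-stacks
  (per pixel, keep the slice with the strongest local-neighbourhood
  intensity variance), intensity segmentation with watershed splitting,
  and a 300-px debris filter.
- **Features** — shape / moment / intensity / multi-scale Haralick
  texture features per organoid (via EBImage), the well-definedness
  filter (drop any feature whose median absolute deviation over the
  dataset is 0, and texture offsets larger than the smallest organoid),
  per-batch centering, and incremental PCA to 25 components.
- **Landscape** — UMAP embedding (min_dist 0.1, 15 neighbours), leiden
  clustering on a shared-nearest-neighbour graph, and dose-dependent
  principal-curve trajectories with pseudotime anchored at the
  DMSO-dense end.
- **Viability** — per-line live/dead random-forest classifiers (10
  trees) anchored on DMSO vs high-dose bortezomib / SN-38 controls
  with a 60/40 split, channel-ablation support, well-level viability
  scores, robust loess plate normalization for CTG luminescence, and
  three-parameter Hill dose-response fits with a normalized AUC
  (`v(c) = E_inf + (1 − E_inf)/(1 + (c/EC50)^h)`, `E_0 = 1`; AUC is
  the mean of `1 − min(v, 1)` over the tested log10-dose range).
- **Drug activity** — per line × drug L2-logistic drug-effect profiles
  against DMSO in PC space (50/50 split, 5-fold CV penalty search,
  10-fold CV AUROC), activity calls at mean AUROC > 0.85, cosine
  clustering of activity-scaled concatenated profiles, and bottom-up
  Fisher mechanism-of-action enrichment over the dendrogram
  (minimum node size 3, BH correction).
- **Factors** — a five-view latent factor model (organoid size from a
  two-component log-normal mixture of DMSO areas, binary mutations,
  top-10%-CV expression, mean DMSO morphology, drug-activity AUROCs)
  fitted by alternating least squares with k = 3 factors, per-view
  variance decomposition, projection of drug-induced phenotypes onto
  learned factors via the loading pseudoinverse, preranked GSEA with a
  permutation null, and drug-target ANOVA on loadings.

Real organoid imaging data of this kind is restricted-access, so the
package includes a first-class synthetic-data module
(`generate_plate_layout()`, `simulate_image_stacks()`,
`simulate_feature_table()`, `simulate_multiview()`) that emulates every
input — plate layouts with controls, rendered cystic/solid organoid
stacks with ground-truth masks, per-organoid feature tables with
line-specific bimodal size mixtures, MoA-grouped shift directions and
dose-dependent death fractions, and a 22-sample × 5-view dataset from a
known 3-factor model. Every stage is tested against that ground truth
or against independent brute-force oracles.

## Worked example

The numbered scripts under `analysis/` run the whole pipeline on a
simulated three-line screen. For instance, fitting the multi-view
factor model and projecting perturbed phenotypes:

```sh
Rscript analysis/06_factors.R
```

prints

```
variance explained (%) per factor and view:
         size mutations expression morphology drug_activity
factor_1 37.4      18.1       52.9       45.8          56.9
factor_2 57.0      20.6       28.3       35.0          24.8
factor_3  0.1      15.9       11.7       11.2          11.2
max |cor| with generating factors: 0.999, 0.997, 1
mean projected factor-1 shift under morphology perturbation: 2.00
GSEA of the synthetic signature on factor-2 loadings: ES = 0.99, NES = 3.87, p = 0.0002
```

Reading this: the three fitted factors each match one generating factor
almost perfectly (|cor| ≥ 0.997); the variance-explained table shows
how much of each view each factor captures (here one factor is
size-dominated, mirroring how organoid size organizes real screens);
shifting every morphology profile by twice the first morphology loading
moves the projected factor-1 score by exactly 2, confirming the
pseudoinverse projection is calibrated; and a gene set built from the
top of the true loading ranking is recovered with near-maximal
enrichment. The earlier steps (`01`–`05`) simulate the screen, run
projection/segmentation/feature extraction on rendered image stacks,
build the UMAP landscape with a dose trajectory, train live/dead
classifiers (validation accuracy 1.00 on separable controls; DMSO
median viability anchored at 1.000 after CTG normalization), and
recover the three simulated MoA groups with adjusted Rand index 1 and
all targets enriched at FDR < 0.01. Each step writes tidy tables under
`results/`.

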