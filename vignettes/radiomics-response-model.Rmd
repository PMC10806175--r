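---
title: "A wavelet radiomics model for chemoradiotherapy response and prognosis"
author: "RadCRT authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A wavelet radiomics model for chemoradiotherapy response and prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The modelling problem

Roughly half of esophageal squamous cell carcinoma patients treated
with definitive chemoradiotherapy do not achieve a complete response,
and responders live substantially longer than non-responders. The
clinical question RadCRT addresses is whether a pre-treatment CT scan
of the tumor already carries enough textural signal to predict, before
therapy starts, (a) who will respond and (b) who will progress early.

The package implements the full analysis chain: a synthetic CT cohort
generator with a planted class effect, image preprocessing, an
undecimated 3D wavelet filter bank, 476 hand-written radiomic features,
AUC-based feature selection, five classifiers compared by DeLong tests,
and a Kaplan–Meier / Cox prognosis module keyed to the model's
prediction score.

# The feature model: 476 features

Each tumor yields one feature vector with the structure

* **8 shape features** computed once from the resampled binary mask:
  volume, surface area, surface-to-volume ratio, sphericity,
  compactness (two definitions), spherical disproportion, and the
  maximum 3D diameter over exposed surface voxels.
* **9 image components**: the original region of interest (`ROI`) plus
  the 8 subbands (`LLL` … `HHH`) of a one-level undecimated 3D wavelet
  decomposition. Subband names give the filter applied along x, y, z in
  that order.
* Per component, **10 histogram features** (energy, entropy,
  uniformity, mean, population variance, skewness, Pearson kurtosis,
  minimum, maximum, range) and **42 texture features**: 22 from the
  gray-level co-occurrence matrix (GLCM), 11 from the run-length matrix
  (GLRLM), 9 from the size-zone matrix (GLSZM).

Total: 8 + 9 × (10 + 42) = **476**. Feature identifiers concatenate
component and feature name (`LLLEnergy`, `ROIGCorrelation`,
`HHLVariance`, …); `featureCatalog()` enumerates all of them with
family and component metadata.

GLCM and GLRLM matrices are built for the 13 unique 3D directions at
distance 1; features are computed per direction and averaged. The GLSZM
uses a single matrix of 26-connected iso-intensity zones (union-find).
Features whose definition degenerates (e.g. GLCM correlation with a
single gray level) propagate `NA` rather than a fabricated value, and
the selection stage drops such features explicitly with a warning.

# Preprocessing

1. **Crop** to the mask bounding box plus an 8-voxel margin, so the
   wavelet filters see real context around the tumor.
2. **Wavelet decomposition** on the native grid (before resampling, so
   the filters act on the acquired voxels).
3. **Resampling** of every component to 2-mm isotropic voxels —
   trilinear for images, nearest-neighbour for the mask. All components
   share one interpolation plan, so voxel correspondence across
   components is exact.
4. **Quantization** with a fixed bin width of 25 intensity units
   anchored at the in-mask minimum: level = ⌊(I − min)/25⌋ + 1. Fixed
   bin width (rather than a fixed level count) keeps the intensity
   resolution comparable across cases and components.

The wavelet transform is separable and undecimated (no down-sampling),
with symmetric half-sample boundary padding and centered filter
alignment, so every subband stays on the input grid. The default basis
is Coiflet-1; Haar is available and used in tests because its short
support makes hand-computed expectations practical. Filter coefficients
are hard-coded constants; the high-pass is derived by the standard
quadrature-mirror relation.

# Feature selection

On the training cohort only:

1. **Screening**: per-feature Mann–Whitney AUC against the response
   label (ties counted ½), with a normal-approximation rank-sum p-value.
   Features with AUC ≥ 0.7 and p < 0.05 survive. AUCs are reported
   unflipped, so the threshold is one-sided by default; a two-sided
   option exists.
2. **Correlation grouping**: screened features are grouped greedily in
   descending-AUC order; a feature joins the existing group whose seed
   it correlates with at |r| ≥ 0.7 (Pearson, p < 0.05), otherwise it
   founds a new group. The highest-AUC member of each group is its
   representative, and the representatives form the model's feature
   set. A connected-components variant is provided for comparison; the
   greedy variant is the default because it keeps group seeds
   interpretable as the strongest markers.

# Classifiers and evaluation

Five algorithms are trained on the selected features: random forest
(500 trees, √p variables per split), naive Bayes, ridge regression
(cross-validated penalty on a fixed 10^2…10^−4 grid with a seeded fold
assignment), a single-hidden-layer neural network (8 units, weight
decay 0.01), and an RBF support-vector machine with Platt-scaled
probabilities. Inputs to the ridge, network and SVM are z-scored with
training-cohort statistics; the same statistics are applied at
validation time.

Training-cohort performance for the random forest uses **out-of-bag**
scores — each case is scored only by trees that never saw it — which
avoids the resubstitution optimism the other models' training ROC
necessarily carries (their score source is flagged in the output).
Validation-cohort performance is fully held out. Models are compared
pairwise with DeLong's test for correlated ROC curves (placement-value
formulation, written in the package and cross-checked against pROC in
the tests). The operating point is the Youden-optimal cutoff of the
random-forest training scores, searched over midpoints of adjacent
unique scores; ties prefer higher sensitivity.

# Prognosis

The prediction score dichotomizes patients at the Youden cutoff into
High and Low groups. For progression-free and overall survival the
package computes Kaplan–Meier curves and medians (first time with
S ≤ 0.5; `NA` when not reached), a log-rank test between score groups,
univariate Cox models for seven variables (age group, sex, T stage
T1–2 vs T3–4, N stage N0–1 vs N2–4, SCC antigen ≤ 1.5, tumor location,
score group), and a multivariate Cox over the univariately significant
(p < 0.05) variables. Cox fits use the Efron tie correction; monotone
likelihood (a group with no events, common at n = 44) is detected and
flagged rather than hidden.

# The synthetic cohort generator

Because real CT scans cannot ship with the package, `generateCohort()`
simulates a cohort whose defaults mirror the study design: 27 training
and 17 validation cases with 6 responders each, on a 48 × 48 × 24 grid
at 0.976 × 0.976 × 2.5 mm voxels.

Each case is an ellipsoidal tumor (jittered radii) filled with a
stationary Gaussian random field: white noise smoothed by a separable
Gaussian kernel whose width is the class's correlation length, rescaled
to the class's intensity standard deviation and offset by its mean HU.
Responders get finer-grained, higher-variance, slightly smaller tumors
(mean 35 HU, SD 55, correlation length 4 mm) than non-responders
(mean 60 HU, SD 20, correlation length 1 mm), planting a texture-plus-
intensity effect that the wavelet features can detect. The background
is homogeneous tissue at −700 HU with mild noise.

Survival follows the response label: progression-free survival is
exponential with median 6 months scaled by a responder hazard ratio of
0.12; overall survival adds an independent exponential gap, so OS ≥ PFS
by construction; both are administratively censored at 90 months.
Covariates (stage, SCC antigen, age, sex, location) are drawn with
class-dependent distributions so the univariate Cox table is non-trivial.

**Realism and limits.** The phantom reproduces the *statistical*
structure the pipeline needs — class-dependent texture spectra,
realistic voxel anisotropy, censored survival tied to response — but
not anatomy: no organ boundaries, no partial-volume mixtures, no
acquisition artifacts. Effect sizes are deliberately strong (the design
question is whether the pipeline recovers a planted effect at n = 44,
not how small an effect it could detect). Results on the synthetic
default cohort therefore sit near the optimistic end of the reported
clinical performance.

# Numerical choices

* All randomness flows from one master seed through a deterministic
  sub-seed schedule, so every artifact of a run is bit-reproducible.
* The configuration (spacing, bin width, basis, thresholds, cohort
  settings) is hashed; feature tables carry the hash and downstream
  phases refuse artifacts produced under a different configuration.
  Training/validation case-id overlap likewise aborts validation.
* Problem sizes (grid 48 × 48 × 24, 44 cases) are the package's own
  choice, set once so a full pipeline run takes well under a minute.
* Matrix builders are vectorized over shifted arrays (no per-voxel R
  loops); the GLCM marginals use `rowsum()` over difference/sum
  indices.

# A minimal run

```{r run, eval = FALSE}
library(RadCRT)
cfg <- pipelineConfig(seed = 1)
res <- runPipeline(cfg, tempfile("radcrt"))
res$validation$roc$RF$auc
res$prognosis$all_cases$pfs$logrank$p_value
```

See the README for a worked example with printed output, and
`scripts/acceptance.R` for the end-to-end reproduction script.
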