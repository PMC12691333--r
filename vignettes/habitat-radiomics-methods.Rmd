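---
title: "Habitat radiomics: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat radiomics: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Solid tumors are not homogeneous: contrast-enhanced CT of a lung tumor
typically mixes poorly enhancing (necrotic/hypoxic) tissue with strongly
enhancing, vascularized tissue. Habitat imaging partitions the segmented
tumor (the VOI) into subregions with distinct imaging phenotypes and
quantifies each separately, on the premise that the *spatial composition* of
these habitats carries prognostic signal that whole-tumor averages wash out.
`habikit` implements that full analysis for 3D CT volumes with binary tumor
masks: per-voxel feature maps, population-level clustering into habitats,
radiomics feature extraction per region, feature selection, a linear
radiomics score ("radscore"), and logistic prediction models compared by
paired ROC analysis. A seeded phantom generator provides cohorts with known
ground truth so every stage is testable without patient data.

## Habitat partitioning

Each tumor voxel is described by two features: its attenuation (HU) and the
Shannon entropy (base 2) of the gray-level histogram over its local
neighbourhood intersected with the mask,

$$H(v) = -\sum_{i=1}^{N_g} p_i \log_2(p_i + \epsilon),$$

with `N_g = 32` bins fixed per patient over the masked HU range and
`eps = 1e-12` inside the logarithm as a guard for empty bins (a constant
neighbourhood therefore gives |H| below `log2(1 + eps)` instead of NaN).
Voxels from all *training* patients are pooled, each column z-standardized
with the pooled mean and SD (HU and bits are incommensurate scales, and
unstandardized Euclidean k-means would be dominated by HU), and clustered
with Lloyd's k-means (k-means++ initialization, best of `n_init` restarts by
inertia, deterministic under a seed). The habitat count is chosen by the
Calinski–Harabasz index

$$CH(k) = \frac{B/(k-1)}{W/(n-k)},$$

maximized over a candidate range (ties toward smaller k). Held-out patients
are projected with the frozen training standardization and assigned to the
nearest frozen centroid — no information flows from validation voxels into
the partition.

**Entropy window.** The neighbourhood radius is a parameter
(`entropy_map(window = )`), default **1 voxel** (a 3×3×3 cube), with a
`per_slice` 2D mode available. We deliberately use the small window: local
entropy is itself a smoothed field, and with larger windows (radius 2 and
up) each habitat's voxel cloud stretches into a long filament along the
entropy axis — boundary neighbourhoods mix habitats over a wider band — and
dispersion-ratio criteria such as CH then favour slicing those filaments,
systematically over-partitioning. With radius 1 the neighbourhood support
stays compact relative to habitat scale and CH recovers the planted habitat
count reliably on phantoms.

**Habitat identity.** k-means cluster ids are arbitrary, so habitats are
renumbered cohort-wide by ascending centroid mean intensity: `Sub1` is
always the lowest-attenuation (necrosis-like) habitat. All downstream
feature names and models depend on this canonicalization being stable.

## Radiomics features

Features are extracted per region (whole tumor, then each habitat, prefixed
`Sub1_`, `Sub2_`, ...) as `{filter}_{family}_{feature}`. The shipped default
manifest — a versioned JSON that is the single source of truth for feature
counts — totals **1218 features per region**: 14 shape features plus 14
filtered images (original, Laplacian-of-Gaussian at σ = 1–5 mm, and 8
undecimated wavelet subbands) × 86 features (18 first-order, 22 GLCM, 16
GLRLM, 16 GLSZM, 9 GLDM, 5 NGTDM). Conventions that matter for
reproducibility:

* **Discretization**: fixed bin width 25 HU for the original image (HU is a
  calibrated scale); fixed bin count 32 for filtered images, whose
  intensities are not HU.
* **Aggregation**: GLCM/GLRLM features are computed per offset/direction
  (the 13 unique distance-1 3D directions) and averaged, not merged.
* **Connectivity**: 26-connectivity for size zones and dependence
  neighbourhoods; GLCM distance fixed at 1 voxel.
* **GLDM dependence**: the dependence of a voxel is the count `d` (0–26) of
  in-mask 26-neighbours within `alpha` (default 0) gray levels of it;
  emphasis weights use `d` itself, with `d = 0` rows contributing zero to
  dependence-weighted sums.
* **Wavelets**: one-level stationary separable transform, Coiflet-1,
  symmetric padding; subband letters name the (z, y, x) axis filters in that
  order. A decimated orthonormal Haar mode exists for energy-conservation
  checks.
* **LoG**: spacing-aware separable Gaussian smoothing followed by the
  discrete Laplacian; responses on constant and affine images vanish in the
  interior, and the blob response matches the closed-form
  Gaussian-convolution result.
* **First order**: percentiles use midpoint interpolation (R `quantile`
  type 5), kurtosis is the non-excess moment ratio `m4/m2²`.
* **Degenerate regions** keep the table rectangular via documented
  sentinels: GLCM Correlation → 1 on a single gray level, kurtosis/skewness
  → NaN on constant regions, regions under 8 voxels are flagged
  low-confidence rather than dropped.

## Feature selection and the radscore

Selection proceeds in strictly nested stages: (1) optional stability
filtering — two-way mixed-effects absolute-agreement single-measure ICC
between readers and/or repeat extractions, pass at ICC ≥ 0.70; (2) greedy
redundancy elimination so the surviving set has pairwise |Pearson r| ≤ 0.75,
scanning features by outcome relevance with lexicographic tie-breaks;
(3) mRMR ranking (mutual-information difference on quantile-discretized
features) to a top-m shortlist (default 50) — running mRMR before LASSO is
the standard radiomics order, letting the penalized fit finalize a
shortlist rather than 10³+ columns; (4) L1-penalized logistic regression
with stratified cross-validation (10-fold default, 5-fold switch), λ chosen
by CV deviance (`lambda.min` default, `lambda.1se` option). The radscore is
the linear combination `intercept + Σ coef·feature` using the penalized
coefficients directly (no refit). Two fixed reference radscore models ship
as named fixtures (`paper_voi`, 6 whole-tumor features; `paper_sub`, 7
subregional features); each is defined as a plain linear combination, so
with all inputs zero it returns its intercept — the package's exact-value
regression anchor.

## Prediction models and evaluation

Three logistic models are compared: clinical (age ≥ 65, N2 stage, any gene
mutation, EGFR mutation — the standard dichotomized risk factors),
whole-tumor radscore, and habitat radscore. Evaluation reports the
Mann–Whitney AUC (half credit for ties), a 95% CI from the DeLong
structural-component variance, the Youden-optimal operating point (ties
resolved toward higher specificity), accuracy, and the AIC of the
univariable logistic fit. Paired AUCs are compared with DeLong's test
(identical ranks ⇒ Z = 0, p = 1); AICs are reported side by side, since
DeLong's test is defined for AUCs only. Calibration curves use equal-width
probability bins; decision curves report
`NB(pt) = TP/n − (FP/n)·pt/(1−pt)` against treat-all and treat-none.
Two-sided p-values throughout; no multiplicity correction is applied.
The 70/30 training/validation split is random, stratified by outcome,
seeded.

## The phantom generator

`phantom_spec()`/`generate_cohort()` produce ellipsoidal tumors (semi-axes
drawn from 6–12 mm by default, 1 mm isotropic) whose interior is divided
into `k_true` contiguous habitats — Voronoi cells of random interior seeds
by default (patchy phenotype), or concentric equal-volume shells (ring
enhancement) behind a flag. Habitat `h` gets intensity
`mean_hu[h] + sd_hu[h] · GRF(corr_mm[h])`, a Gaussian random field with unit
variance and habitat-specific correlation length. Defaults (mean 0/80/160
HU, sd 5/12/25 HU, correlation 0.1/0.45/0.25 mm) describe an
arterial-phase-like lesion from necrotic core to strongly enhancing tissue;
means are separated by at least twice the largest sd, a generator guarantee
asserted at construction, so the planted habitats are separable in
(intensity, entropy) space. Entropy contrast between habitats is driven
mainly by noise amplitude (how many histogram bins the local noise
occupies); correlation lengths are kept mild because strong smoothing
(≳1.5 mm) collapses local entropy toward zero for that habitat and the
planted structure stops being recoverable — a property of local-entropy
features worth remembering with real data too.

The enhancing habitat's noise SD gets a per-patient multiplier (uniform
1 ± 0.4), so subregional texture carries genuine patient-level signal. The
binary outcome is Bernoulli under a logistic link on habitat volume
fractions plus that subregional texture summary (defaults `f1 = −4`,
`f3 = +5`, `tex = +1.5` on the standardized summary) with small effects on
four clinical flags; the intercept is calibrated by root-finding so the
link's mean equals the requested prevalence (0.35 default). This link gives
the habitat model a true advantage: the whole-tumor model can see habitat
composition through mixture summaries (e.g. mean HU), but the subregional
texture term is essentially invisible to it, mirroring the headline
contrast habitat analyses report. One global seed streams into per-patient
substreams, so cohorts are bit-reproducible and extendable.

A second reader's mask is simulated by optional one-voxel morphological
dilation/erosion plus random boundary flips, with a guaranteed Dice floor
against the original.

**What the phantoms do not emulate:** scanner physics and reconstruction,
contrast kinetics, atelectasis or vessels abutting the tumor, non-ellipsoidal
morphology, and inter-scanner variability. Passing phantom tests shows the
pipeline recovers planted structure under its own generative assumptions; it
does not certify performance on real CT.

## Numerical choices and problem sizes

Resampling is trilinear for images and nearest-neighbour for masks;
mask/image grid mismatches are hard errors. k-means asserts its inertia is
non-increasing across Lloyd iterations on every run; an emptied cluster is
re-seeded at the farthest point. CH with zero within-dispersion returns
`Inf`. Greedy stages break ties deterministically (column order after a
lexicographic sort).

The test suite exercises the pipeline at deliberately modest sizes chosen to
make the Monte-Carlo assertions stable: 20-patient cohorts over 20 seeds for
habitat-count recovery; 10 pipeline replicates at n = 100 with a reduced
manifest for the model-ordering property; 2000 null replicates at n = 100
for DeLong size; 200 random volumes for matrix conservation laws. The full
1218-feature manifest is exercised on a single ~30-mm phantom.

## Limitations

Hard k-means cannot represent transition zones between habitats; the
CH-selected k is a global cohort property, not per-patient; the correlation
filter and mRMR operate marginally and can drop jointly informative pairs;
and penalized coefficients are used unrefit, so radscores are on the scale
the penalty produced, not calibrated log-odds (downstream logistic fits
absorb this affinely). CH-based selection is also scale-sensitive in a
subtler way: when very many voxels are pooled and per-patient texture
variability widens a habitat's feature cloud, the index can justify
splitting that habitat, so the recovered k should be read as a
cohort-level description under the documented conditions rather than an
absolute biological count — the same caution applies to real cohorts.
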