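---
title: "Delta-radiomics texture analysis and survival modelling with deltarad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delta-radiomics texture analysis and survival modelling with deltarad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltarad)
```

## The problem

Patients with hormone-receptor-positive metastatic breast cancer and liver
metastases are monitored with serial contrast CT while on CDK4/6-inhibitor
plus endocrine therapy. Anatomic (RECIST-style) size change is a late and
noisy readout of benefit; the micro-architectural appearance of a lesion and
of the tissue immediately around it often changes earlier. `deltarad`
implements a *delta-radiomics* pipeline for this setting: quantitative
texture descriptors are computed on the baseline scan and again a few cycles
into therapy, their change (post minus pre) is the feature set, a penalized
Cox model compresses that set into a radiomic risk score (RRS) for overall
survival, and a linear discriminant classifier predicts response from the
same selected features. Because no patient data ship with the package, a
synthetic phantom cohort generator with a *planted* texture-change effect
stands in for the clinical cohorts; every stage of the pipeline is exercised
and validated against that known ground truth.

## Regions: tumor and fat-excluded peritumoral rim

Texture is measured in two compartments: inside the lesion mask, and in a
peritumoral rim obtained by dilating the lesion boundary outward by a
physical distance (default 12 mm) and subtracting the lesion. Dilation is
computed with an exact Euclidean distance transform that honours anisotropic
voxel spacing — in-plane resolution is ~1 mm while slice thickness is 1–3 mm,
so voxel-count dilation would bias the rim shape along z. Peri-hepatic fat
(roughly −100 to −10 HU, much lower attenuation than liver parenchyma) does
not belong to the tumor microenvironment, so any rim voxel at or below the
fat upper bound (−10 HU) is excluded; this removes air as well, which is even
lower. The number of voxels removed is reported. A rim that is empty after
exclusions is flagged, and all rim features downstream become missing values
rather than silent zeros. The rim is not additionally clipped to a liver
mask: on real data the HU rule removes fat and air but not, say, adjacent
kidney; that residual impurity is a known limitation.

## The texture bank: 111 response maps, 5 statistics, 2 regions

All texture is computed in 2D, slice by slice, on every slice where the
region has pixels, and per-pixel responses are pooled across slices before
summarising. Four filter families give 111 response maps:

* **13 Haralick features** from gray-level co-occurrence matrices (GLCMs).
  Intensities are quantized to 64 equal-width levels over the region's own
  intensity range; pairs are counted at the four unit-distance offsets
  (0,1), (1,1), (1,0), (1,−1), symmetrized, and normalized. The 13 classical
  statistics (angular second moment, contrast, correlation, sum-of-squares
  variance, inverse difference moment, sum average/variance/entropy, entropy,
  difference variance/entropy, and the two information measures of
  correlation) use base-2 logarithms with 0·log 0 := 0. At the region level
  (`compute_glcm()` + `haralick_features()`) features are averaged over the
  four offsets. For the *per-pixel* response maps that feed the summary
  statistics (`haralick_response_maps()`), a local GLCM is accumulated in a
  5×5 window around each region pixel with all four offsets pooled into one
  matrix — pooling is used there because a 5×5 window contributes only a few
  dozen pairs per offset, too few for four stable separate estimates. Both
  code paths share one tested feature kernel.
* **25 Laws maps**: cross-correlation with the 5×5 kernels formed as outer
  products of the level/edge/spot/ripple/wave vectors L5, E5, S5, R5, W5.
  Raw responses are used (not windowed energy): the five region statistics
  already aggregate over pixels, so an extra local energy window would
  double-smooth.
* **25 Laws-Laplacian maps**: the slice is first smoothed with a zero-sum
  Laplacian-of-Gaussian (σ = 1 px), then the same 25 Laws kernels are
  applied.
* **48 Gabor maps**: magnitudes of complex Gabor responses for 8 orientations
  (steps of π/8) × 6 wavelengths {2, 4, 6, 8, 10, 12} px, isotropic Gaussian
  envelope with σ = 0.56·wavelength, envelope-weighted DC correction so a
  constant image gives exactly zero response. This parameterization realizes
  exactly 48 maps; only the count is externally fixed, the grid is a design
  choice exposed in the configuration.

All convolutions use symmetric (edge-inclusive) reflection padding so lesion
crops do not create artificial edges, and are evaluated by FFT; responses
carry ~1e−12 relative numerical noise, which the tests tolerate explicitly.

Each map is summarised per region by five first-order statistics of the
pooled pixel values: mean, median, SD (n−1 denominator), skewness and
*excess* kurtosis (standardized sample moments). A zero-variance map has
skewness and kurtosis 0 by convention. That yields 111 × 5 = **555 texture
statistics per region** and **1110 across tumor + rim** — the structural
counts the whole pipeline is built around.

## Shape: 24 descriptors

Twenty-four 3D shape features are computed from the tumor mask in physical
units; the exact list is frozen in `deltarad:::shape_feature_names` (volume
in mL, surface area, surface:volume, sphericity, two compactness variants,
maximum 3D and per-plane 2D diameters, principal axis lengths with elongation
and flatness, equivalent-sphere diameter, bounding-box extents and fill
fraction, centre-of-mass offset, slice count, mean slice area, largest-slice
perimeter). Surface area uses a coarea estimator: the binary mask is smoothed
with a small Gaussian (σ = 0.8 mm) and the integral of the gradient magnitude
of the smoothed indicator estimates the average level-set perimeter. On
digitized balls of radius 5–10 voxels this is accurate to within about 1%
(face counting would overestimate a sphere by ~50%); on thin rod-like masks
it underestimates area by 10–20% because opposing faces are closer than the
smoothing scale, so sphericity of very thin structures is biased upward. σ =
0.8 mm was chosen from a discretization study over balls (isotropic and
1×1×3 mm anisotropic) and rods; sphericity is clamped to (0, 1]. Axis lengths
are 4·sqrt of the eigenvalues of the voxel-coordinate covariance; the
largest-slice perimeter is the grid perimeter (exposed pixel-edge lengths),
which for smooth contours is a known overestimate of the geometric perimeter
but is a stable, monotone descriptor.

## Normalisation and deltas

Feature values are z-scored with means and SDs estimated on the **pooled
pre+post training rows** — pooling keeps the two timepoints on one scale so
their difference is meaningful; per-timepoint normalization would absorb
exactly the global shift the delta is supposed to measure. (Either reading is
defensible; the alternative `order = "delta_first"` — difference raw values,
then standardize the deltas — is available in `build_delta_table()` for
sensitivity analyses.) Zero-variance features are dropped with a warning.
Validation cohorts are always transformed with the training statistics; the
tests assert their column means are *not* re-centred. The delta table is
post − pre per feature, plus the raw tumor volume change in mL as its own
column.

## The radiomic risk score

`fit_rrs()` (alias `fit_lasso_cox()`) fits an L1-penalized Cox partial
likelihood over the delta features by coordinate descent (glmnet). The
penalty is chosen on a grid of 100 log-spaced values by cross-validation
with `min(n_folds, n)` folds — with the default request of 100 folds and a
training cohort of a few dozen patients this degenerates to leave-one-out,
the only feasible reading of very-many-fold CV at that scale. Two CV criteria
are offered:

* `"deviance"` (default): cross-validated Cox partial-likelihood deviance,
  the statistically meaningful criterion for a censored outcome;
* `"mse_linear_predictor"`: held-out mean squared error between the linear
  predictor and a centred −log(time) surrogate. A literal mean-squared-error
  criterion is not well defined for Cox regression; this option exists so the
  effect of that reading can be examined.

The default grid floor is 0.01·λ_max rather than deeper: below that the Cox
path saturates whenever features outnumber events, coordinate descent becomes
numerically fragile and slow, and in every study condition we examined the CV
optimum lies well above the floor. An explicit `lambda_grid` overrides this.

The RRS of a patient is the linear combination of the selected delta features
with their coefficients. Patients are stratified at the **median training
RRS**; validation cohorts are always split at the training cutoff, never
their own median, and a score exactly at the cutoff goes to the low-risk
group. Evaluation uses Kaplan–Meier curves with the log-rank test, Cox
hazard ratios with Efron tie handling and Wald intervals, and Harrell's
concordance (tied scores credit 0.5; a pair is usable when the shorter
observed time is an event).

## Nomogram, calibration, decision curves

`build_nomogram()` fits a multivariable Cox model over the RRS and clinical
covariates (age, race, baseline tumor volume) and assigns each covariate a
point scale proportional to its coefficient times its observed range (widest
contribution = 100 points); total points map to the predicted probability of
surviving to the horizon (default 36 months) through the baseline survival
estimate. Calibration groups patients into deciles of predicted risk, merges
groups smaller than two subjects with a neighbour, compares mean predictions
with the Kaplan-Meier-observed event proportion at the horizon (this is how
censoring enters a test originally defined for logistic regression — the
adaptation is ours and is stated as such), and reports a Hosmer–Lemeshow
χ² with groups − 2 degrees of freedom. A calibration-under-truth simulation
(exponential survival, n = 400, 10 deciles) shows this reference is mildly
anticonservative for the survival adaptation — about 13% of self-consistent
datasets fall below p = 0.05 rather than the nominal 5% — so borderline HL
p-values should not be over-read. Optimism of the concordance index is
estimated with 500 bootstrap refits by default (the per-resample trace is
kept so the count is auditable). Decision-curve analysis reports net benefit
`TP/n − FP/n · t/(1−t)` on the grid t = 0.01…0.99 (step 0.01) against
treat-all and treat-none references.

## Response classification

The classifier is a two-class pooled-covariance linear discriminant written
out explicitly (`solve(S, μ₁ − μ₀)`), with ridge shrinkage toward the scaled
identity applied at the smallest weight that makes the pooled covariance well
conditioned — this is what lets the model fit when features are collinear or
p ≥ n. Responders are CR/PR/SD; non-responders are PD. Features entering the
classifier are the LASSO-selected prognostic features. Training performance
is summarised by 100 iterations of stratified three-fold cross-validation
(AUC per iteration = mean over its folds; percentile interval over
iterations); the operating threshold is fixed on the training scores by the
Youden index and is never recomputed on a holdout. Holdout AUC carries a
DeLong confidence interval.

## The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` builds paired pre/post phantoms per patient: a noisy
liver-like background (≈55 ± 6 HU), an ellipsoidal hypodense lesion (≈30 HU
mean) whose interior carries a Gaussian random field smoothed to a 3 mm
correlation length, and an optional fat band (HU uniform in [−100, −10])
placed 2–6 mm from the lesion so the rim's fat exclusion is actually
exercised. The planted per-patient covariate u ~ N(0, 1) scales the
post-minus-pre change of the field amplitude (3 HU per unit), survival is
exponential with log-hazard `effect_beta · u` around a baseline hazard of
log(2)/19 per month (a ~19-month median, matching the clinical setting), and
the patient is a non-responder iff u exceeds the 65th normal percentile
(≈65% responders). Administrative censoring times are uniform on [0, 48]
months and drawn with probability `censoring_rate` (0.25 by default);
`censoring_rate = 0` means no censoring at all. The default cohort size is
32, the size of a single-site training cohort in this setting; volumes
default to 64×64×24 voxels at 1×1×3 mm so a cohort extracts in minutes.
Several validation studies in the tests use reduced 48×48×16 phantoms and
matrix-level cohorts (`simulate_feature_cohort()`) to keep runtimes at
desk scale; the problem sizes are stated in each test.

What passing tests on these phantoms shows: the geometry (rim construction,
shape), the counting identities, the planted-effect recovery (amplitude
changes are picked up by Haralick entropy; the LASSO finds planted columns;
the survival stack has nominal type-I error and real power) and end-to-end
determinism. What it cannot show: robustness to scanner/kernel variation,
registration error between timepoints, segmentation variability, non-
exponential hazards, or lesions with realistic anatomy — phantom lesions are
smooth ellipsoids with stationary texture. Conclusions about clinical
performance require clinical data.

## Numerical conventions and degenerate inputs

* HU outside [−1024, 3071] are clipped on ingest with a warning.
* Quantization of a constant region maps everything to level 1; a GLCM with
  no valid pair is flagged missing and its features are NA.
* Correlation and IMC1 are 0 when a GLCM marginal is degenerate.
* Empty rims flag all rim features missing; they are never zero-filled.
* `sd = 0` columns are dropped at normalization, not imputed.
* Full LASSO shrinkage (no features selected) gives RRS ≡ 0 for everyone and
  a cutoff of 0; the model object prints this state explicitly.
* Constant classifier scores give AUC 0.5 by the tie convention and a
  flagged degenerate threshold.
* All seeds are derived per stage from one master seed via a 32-bit FNV-1a
  stream hash, so every stage is independently reproducible and two runs
  with the same configuration are byte-identical.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(
  cohort = cohort_config(n_patients = 16, seed = 42),
  n_boot = 100, seed = 42)
res <- run_pipeline(cfg, "runs/demo")
read.csv(file.path(res$fit_survival, "survival_summary.csv"))
```

Stages write per-stage manifests with the configuration hash, package version
and seed; caches are keyed by the hash of exactly the settings a stage
depends on, so changing the rim width re-extracts features but reuses the
phantom cache.
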