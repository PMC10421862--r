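# deltarad

Delta-radiomics texture analysis and survival modelling for longitudinal CT
of liver metastases.

## What problem this solves

In hormone-receptor-positive metastatic breast cancer treated with CDK4/6
inhibitors plus endocrine therapy, anatomic size change on CT is a late
readout of benefit. The texture of a liver lesion and of the tissue
immediately around it changes earlier. `deltarad` is for imaging researchers
who want to quantify that change: it computes intratumoral and peritumoral
texture descriptors on paired (pre- and post-treatment) CT scans, takes their
difference, and models the result against overall survival and treatment
response.

The core quantity is the **radiomic risk score**. For each scan, 111 texture
response maps are computed slice by slice — 13 local Haralick (gray-level
co-occurrence) statistics, 25 Laws kernels, 25 Laws-Laplacian kernels, and a
48-filter Gabor bank — and each map is summarised inside the tumor and inside
a fat-excluded 12 mm peritumoral rim by five first-order statistics (mean,
median, SD, skewness, kurtosis): 555 texture statistics per region, 1110 per
scan, plus 24 3D shape descriptors. After z-normalisation, the post-minus-pre
deltas Δx enter an L1-penalized Cox model of overall survival,

```
RRS_i = Σ_j  β_j · Δx_ij ,        β = argmax  {penalized Cox partial likelihood},
```

with the penalty λ chosen by cross-validation on a 100-point grid. Patients
are stratified at the median training RRS and evaluated with Kaplan–Meier /
log-rank analysis, hazard ratios, and Harrell's concordance index; a clinical
nomogram (RRS + age, race, baseline tumor volume) with bootstrap calibration
and decision-curve analysis quantifies clinical utility, and a pooled-
covariance linear discriminant over the selected features predicts responder
vs non-responder status (100 iterations of stratified three-fold CV).

No patient data ship with the package. A synthetic phantom generator builds
paired CT volumes (liver-like background, textured ellipsoidal lesion,
peri-hepatic fat band) whose survival and response labels are coupled to a
*planted* change in lesion texture heterogeneity, so the entire pipeline is
testable against known ground truth.

## A worked example

```r
library(deltarad)

# 1. simulate a 16-patient cohort of paired pre/post phantoms
cfg <- cohort_config(n_patients = 16, seed = 42)
cohort <- generate_cohort(cfg)
print(cohort)
#> <synthetic_cohort> 16 patients, 15 events, 5 non-responders

# 2. extract features (1110 texture + 24 shape per scan), build deltas
feats <- extract_cohort_features(cohort)
delta <- build_delta_table(feats)$delta
dim(delta)
#> [1]   16 1135    # patient_id + 1110 texture + 23 shape deltas + volume change

# 3. fit the radiomic risk score on the first 10 patients
train_ids <- cohort$clinical$patient_id[1:10]
model <- fit_rrs(delta[delta$patient_id %in% train_ids, ],
                 cohort$clinical[1:10, ], seed = 42)
print(model)
#> <rrs_model> 1 selected feature(s) at lambda = 0.5986 (deviance CV, 10 folds)
#>   training: n = 10, events = 9, C-index = 0.884, median RRS cutoff = -0.1063

# 4. validate on the held-out patients
valid  <- delta[!delta$patient_id %in% train_ids, ]
scores <- compute_rrs(model, valid)
concordance_index(scores, cohort$clinical$os_months[11:16],
                  cohort$clinical$event[11:16])
#> [1] 0.8
groups <- stratify_by_cutoff(scores, model$rrs_cutoff)
km_logrank(groups, cohort$clinical[11:16, ])
#> <km_result>
#>   median survival: low = 190, high = 26.8
#>   log-rank chisq = 5.05, p = 0.0246
```

Reading this output: at a toy cohort size the LASSO keeps a single delta
feature; patients scored above the training-median cutoff (`high`) die
sooner (median 26.8 vs 190 months on this phantom cohort, log-rank p =
0.025), and the score ranks held-out survival with concordance 0.80. (In the
16-patient example the model selected `haralick_idm_mean_tumor` with
coefficient −0.20: the delta of intratumoral co-occurrence homogeneity —
falling homogeneity means rising heterogeneity, exactly what the generator's
planted amplitude change perturbs. One shape delta, `shape_com_offset_mm`,
is dropped from the pool as zero-variance on this cohort, hence 23 shape
deltas.)

The full pipeline — simulate, extract, delta, fit-survival, nomogram + DCA,
classify — runs from one configuration with per-stage caching:

```r
res <- run_pipeline(pipeline_config(cohort = cfg, seed = 42), "runs/demo")
```

or from a shell via the thin wrapper `inst/cli/deltarad.R`:

```sh
Rscript inst/cli/deltarad.R run-all --out runs/demo --seed 42
```

See `vignette("delta-radiomics")` (source under `vignettes/`) for the model,
its assumptions, every tunable parameter, and known limitations.

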