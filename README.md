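# radzone

Region-wise imaging-biomarker analysis for multiparametric prostate MRI.

Pretreatment risk stratification of localized prostate cancer and prediction
of biochemical recurrence (BCR) are both imperfect, particularly after
androgen deprivation therapy has altered the gland's MRI appearance.
`radzone` implements, as a tested and reusable R pipeline, a region-aware
quantitative analysis of the three prostate regions segmented on T2-weighted
MRI — central + transitional zone (CZ+TZ), peripheral zone (PZ), and seminal
vesicles — for researchers evaluating imaging biomarkers against clinical
endpoints.

The pipeline covers:

* **Diffusion**: voxel-wise ADC from multi-b DWI under the mono-exponential
  model `S(b) = S0 exp(-b ADC)` (log-linear least squares), with the five ROI
  statistics `ADC_mean`, `ADC_std`, `ADC_median`, `ADC_p25`, `ADC_p75`.
* **Perfusion**: voxel-wise simplified Tofts fitting of DCE series,
  `Ct(t) = Ktrans ∫ C_AIF(τ) exp(-kep (t-τ)) dτ`, with `ve = Ktrans/kep`,
  a population (or supplied) arterial input function, and 15 ROI statistics
  over the Ktrans/kep/ve maps.
* **Radiomics**: a fixed 105-feature manifest per region — 14 shape,
  18 first-order, 22 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM — with all
  matrix families validated exactly against brute-force enumeration.
* **Whole-gland aggregation**: volume-weighted averages
  (`w_r = V_r / Σ V_s`) for non-shape features; shape recomputed on the
  union mask.
* **Endpoints**: two-group risk mapping (low/favorable-IR vs
  unfavorable-IR/high) and PHOENIX BCR (PSA rise ≥ 2 ng/mL over the nadir
  within 10 years).
* **Statistics**: correlation pruning (|r| > 0.9), Shapiro–Wilk/Levene-gated
  t vs Wilcoxon univariate screening (α = 0.05), then logistic models with
  VIF > 5 elimination, AIC backward selection, and stratified 5-fold
  cross-validation (AUC, accuracy, sensitivity, specificity, LR-test p) for
  3 endpoints × 4 regions × imaging / imaging+clinical variants.
* **Synthetic phantoms**: a seeded generator of full image cohorts (label
  maps, T2w, DWI, DCE, clinical tables) with known ground truth, used to
  validate every stage end to end.

## Worked example

Generate a 20-patient synthetic cohort (30% of patients lack DCE), extract
all features, screen the CZ+TZ features against the BCR endpoint, and build
the BCR model grid:

```r
library(radzone)

cc <- cohort_config(
  n_patients = 20, bcr_fraction = 0.25,
  phantom = phantom_config(grid_shape = c(16, 16, 8)),
  missing_sequence_fractions = list(dwi = 0, dce = 0.3),
  seed = 42)
cohort <- generate_cohort(cc)
#> <phantom_cohort> 20 patients (risk groups 5/15, BCR 5/15)

features <- build_feature_table(cohort)
dim(features)
#> [1]  20 501    # patient_id + 125 features x 4 regions

screen <- screen_features(
  features[, grep("^cztz__", names(features))],
  factor(cohort$clinical$bcr_10y, levels = c("no", "yes")))
head(screen$results[screen$results$significant,
                    c("feature", "test_used", "p_value", "direction")])
#>                                           feature test_used      p_value direction
#> 24           cztz__firstorder__InterquartileRange  t_pooled 3.583975e-02        -1
#> 27  cztz__firstorder__RobustMeanAbsoluteDeviation  t_pooled 2.429246e-02        -1
#> 83     cztz__glszm__SmallAreaLowGrayLevelEmphasis  t_pooled 3.921224e-02         1
#> 106                     cztz__diffusion__ADC_mean  t_pooled 1.517435e-08        -1
#> 107                      cztz__diffusion__ADC_std   t_welch 9.770903e-04        -1
#> 108                   cztz__diffusion__ADC_median  t_pooled 2.004598e-08        -1

grid <- run_all_models(features, cohort$clinical, endpoints = "bcr", seed = 1)
print(grid$summary[, c("region", "variant", "auc", "accuracy", "p_value")],
      digits = 2)
#>   region          variant  auc accuracy p_value
#> 1   cztz          imaging 1.00     1.00 2.1e-06
#> 2   cztz imaging+clinical 1.00     1.00 9.8e-06
#> 3     pz          imaging 0.89     0.90 6.0e-04
#> 4     pz imaging+clinical 0.88     0.84 2.1e-04
#> 5     sv          imaging 0.82     0.75 1.5e-03
#> 6     sv imaging+clinical 0.97     0.95 5.7e-05
#> 7  whole          imaging 0.85     0.80 4.2e-04
#> 8  whole imaging+clinical 0.93     0.95 2.1e-04
```

This cohort was generated with its default injected contrasts — lower CZ+TZ
ADC and higher vesicle heterogeneity in BCR patients — and the screen
recovers exactly that pattern: ADC statistics fall with BCR (direction −1)
and the CZ+TZ region, which carries the ADC contrast, tops the model grid.
`p_value` is the likelihood-ratio test of the selected model against the
intercept-only model; AUC/accuracy come from pooled 5-fold cross-validated
predictions. At n = 20 the region carrying a strong contrast can saturate
at AUC 1.

Cohorts can be written to and read from disk (NIfTI + JSON sidecars +
clinical CSV) with `write_cohort()` / `read_cohort()`, and the whole
analysis runs with one call: `run_pipeline(cohort, pipeline_config(),
out_dir = "analysis/")`. A command-line wrapper with `simulate` / `extract`
/ `screen` / `model` / `all` subcommands is in `inst/cli/radzone.R`.

See the vignette (`vignettes/region-wise-biomarkers.Rmd`) for the models,
conventions and design choices.

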