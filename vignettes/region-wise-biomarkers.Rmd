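---
title: "Region-wise prostate MRI imaging biomarkers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-wise prostate MRI imaging biomarkers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radzone)
```

`radzone` implements a complete region-wise imaging-biomarker analysis for
multiparametric prostate MRI: quantitative map fitting (diffusion and
perfusion), radiomic feature extraction per anatomical region, volume-weighted
whole-gland aggregation, and a two-stage statistical analysis (univariate
screening, then multivariate logistic modelling) against two clinical
endpoints — the two-group pretreatment risk stratification and biochemical
recurrence (BCR) within ten years. A synthetic phantom generator with known
ground truth makes every stage testable end to end.

## The quantitative models

**Diffusion.** The DWI signal follows the Gaussian mono-exponential model
$S(b) = S_0 e^{-b \cdot \mathrm{ADC}}$. `fit_adc()` estimates ADC per voxel by
ordinary least squares of $\log S$ on $b$, which is exact on noiseless
exponentials and fully deterministic. Voxels with a non-positive sample are
flagged invalid rather than clamped; negative slopes from the noise floor are
reported as ADC 0. Five ROI statistics (mean, sample SD, median, p25, p75)
summarise the map per region.

**Perfusion.** DCE curves follow the simplified Tofts model
$$C_t(t) = K^{trans}\int_0^t C_{AIF}(\tau)\, e^{-k_{ep}(t-\tau)}\, d\tau,
\qquad v_e = K^{trans}/k_{ep}.$$
The convolution is evaluated by an exponential-kernel recursion that is exact
when the AIF is treated as piecewise linear between samples
(`forward_tofts()`). Two fitting routes share this convention:

* `fit_tofts()` — bounded nonlinear least squares for a single curve
  ($K^{trans} \in [0,5]$, $k_{ep} \in (0,10]$ min$^{-1}$), restarted from a
  3-point initial grid; $v_e$ is always derived as $K^{trans}/k_{ep}$, never
  fitted.
* `fit_tofts_map()` — the voxel-wise default. It solves the integral form
  $C_t = K^{trans}\int C_{AIF} - k_{ep}\int C_t$ by linear least squares with
  cumulative trapezoidal integrals, vectorised across all voxels. Because the
  forward model is exact for piecewise-linear AIFs and the tissue curve is
  smooth at 3-s sampling, noiseless phantom maps invert to well below 0.1%
  relative error. A `method = "nls"` switch refines each voxel with the
  nonlinear route.

Signal is converted to concentration by linear relative enhancement,
$C(t) = (S(t)-\bar S_0)/\bar S_0 \times \text{scale}$: the acquisition
details needed for absolute T1-based conversion are scanner-specific, and the
analysis is driven by contrasts, not absolute mM. The conversion is pluggable
(`signal_to_concentration(fun = ...)`). Voxels with $v_e$ above a sanity cap
(default 1.2) or non-physical rates are excluded from ROI statistics.

A note on identifiability: with 50 dynamics at 3 s the acquisition covers
2.5 min, of the same order as $1/k_{ep}$ for typical prostate values, so
$k_{ep}$ is estimated with noticeably more variance than $K^{trans}$ under
noise. At 5% per-sample concentration noise the median $K^{trans}$ error is
around 2% while the median $k_{ep}$ error sits near 5%; recovery is therefore
assessed on the pooled error of both rates.

**The AIF.** `population_aif()` provides a population curve: a bi-exponential
washout multiplied by a smooth bolus-arrival ramp so $C_{AIF}(0)=0$.
Measured AIFs can be supplied via `aif_curve()` and flow through every fit.

## The radiomic feature set

`feature_manifest()` fixes 105 features per region: 14 shape, 18 first-order,
22 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM and 5 NGTDM, in a stable order, shipped
also as JSON in `inst/extdata/`. Conventions that matter for reproducibility:

* **Discretisation**: fixed bin count (default 32) over the ROI min–max; the
  maximum maps to the top bin. A constant ROI collapses to one level. Binning
  is intensity-scale-free, which suits arbitrary synthetic intensity ranges.
* **Matrix families**: distance-1 neighbourhoods throughout. GLCM and GLRLM
  are computed per offset/direction over the 13 unique 3D directions and the
  features averaged (not merged); GLSZM zones use 26-connectivity; NGTDM and
  GLDM use the 26-neighbourhood with GLDM dependence tolerance 0.
* **Shape**: the surface mesh is built from the exposed faces of the voxel
  mask, with vertices at voxel corners. Surface area is the summed face area;
  the enclosed volume coincides with the voxel-count volume (so `MeshVolume`
  equals `VoxelVolume` under this convention — both are kept for manifest
  completeness and the correlation-pruning stage removes the duplicate).
  Diameters are vertex-pair maxima (3D, and per slice/column/row planes);
  axis lengths are $4\sqrt{\lambda_i}$ of the physical-coordinate covariance;
  `Elongation` $=\sqrt{\lambda_2/\lambda_1}$, `Flatness`
  $=\sqrt{\lambda_3/\lambda_1}$. A single-voxel mask reports its voxel
  dimensions, flagged degenerate.
* **First-order**: population moments (denominator $N$); skewness/kurtosis of
  a zero-variance ROI are defined as 0; entropy/uniformity use the same
  binning as the matrices. ROI statistics of quantitative maps use sample SD
  and type-7 (linear interpolation) percentiles; the same percentile
  convention is used everywhere.

Every matrix family is validated against independent brute-force enumerators
(naive loops over voxel pairs, runs, zones and neighbourhoods) on random
small ROIs — exact equality, not tolerance agreement.

## Whole-gland aggregation

Non-shape features combine by volume weighting,
$w_r = V_r / \sum_s V_s$ and $F_{whole} = \sum_r w_r F_r$, over the three
regions (CZ+TZ, PZ, seminal vesicles — the vesicles are included, following
the three-ROI definition of the weighting). The result is a convex
combination, so the whole-gland value always lies within the regional range.
Shape features are not averaged: they are recomputed on the union mask,
which is the only choice that keeps diameters geometrically meaningful (a
per-region sum is available behind `shape_mode = "sum"`). Missing regional
values (a patient without DCE) propagate missingness to the whole gland.

## Endpoints

`map_risk_group()` collapses the four risk classes to group 1
(low + favorable-intermediate) vs group 2 (unfavorable-intermediate + high).
`derive_bcr()` applies the PHOENIX rule — BCR at the first PSA rise of at
least 2 ng/mL (inclusive) above the running nadir within the 10-year
horizon. The nadir is the running minimum of all preceding measurements;
appending data after the first qualifying rise never changes the outcome.

## Statistical analysis

**Screening** (`prune_correlated()`, `compare_groups()`,
`screen_features()`): features with pairwise $|r| > 0.9$ are pruned greedily
in manifest order (the later feature of a pair is dropped — the tie-break is
our documented choice, as only the threshold is prescribed). Each surviving
feature is compared between groups: Shapiro–Wilk per group at $\alpha=0.05$
gates normality; Levene's test then chooses pooled vs Welch $t$ (the Welch
guard is configurable off); otherwise the two-sided Wilcoxon rank-sum test is
used, exact for combined $n \le 20$ without ties and normal-approximated with
tie correction above. Significance is $p < 0.05$ with no multiplicity
correction by default (Benjamini–Hochberg available). Type-I error of the
full screen is verified at $\alpha \pm 0.02$ by simulation.

**Modelling** (`vif_filter()`, `backward_select_aic()`, `crossvalidate()`,
`run_all_models()`): candidate variables are the significant screen
survivors (plus, in combined models, ECOG PS, age and perineural invasion —
extended with PSA, ISUP and N stage for the BCR endpoints). Collinearity is
removed by iteratively dropping the largest VIF above 5 (VIF $=1/(1-R^2)$);
variable selection is backward from the full logit GLM, removing the
variable whose removal most reduces AIC until no removal helps, ties broken
toward the later variable. Performance is estimated by seeded stratified
5-fold cross-validation with pooled out-of-fold probabilities: AUC, plus
accuracy/sensitivity/specificity at threshold 0.5 (sensitivity refers to the
event class). The model $p$-value is the full-data likelihood-ratio test
against the intercept-only model — the source procedure does not define its
$p$-value, so this definition is ours and is stated here. Selection happens
on the full data with CV used for performance estimation, mirroring the
source workflow; this is optimistic relative to nested CV, which users can
approximate by re-running selection per fold. Quasi-complete separation
falls back to a lightly ridge-penalised fit (lambda 0.01) for prediction,
flagged in the report. In small cohorts the candidate list is truncated to
the strongest survivors (smallest $p$) so the design stays well posed
($\le n/3$ candidates); at registry scale this guard is inactive.

`run_all_models()` builds the full grid: 3 endpoints $\times$ 4 regions
$\times$ 2 variants = 24 reports.

## The phantom generator

`generate_phantom()` renders one synthetic patient on a common grid
(defaults: 1.6 mm isotropic voxels, b-values 0/500/1000 s/mm², 50 DCE
dynamics at 3 s): three disjoint ellipsoidal regions (central gland,
peripheral-zone shell, seminal vesicles, scaled to the field of view); a
T2w volume with per-region mean, correlated "blob" heterogeneity
(Gaussian-smoothed field with configurable correlation length and
amplitude) and white noise; DWI decaying with each region's true ADC; DCE
signal synthesised through the same Tofts forward model and enhancement
relation the analysis inverts. Noise is Gaussian on magnitude by default
(Rician optional); default DWI noise corresponds to SNR 50.

`generate_cohort()` adds the population structure: exact two-group risk
sizes (default 25% group 1, reproducing 32/96 at $n=128$, with class
composition 6/26/31/65), exact BCR counts (default 20/128), missing
sequences (defaults: DWI absent in 21/128, DCE in 66/128), per-patient
biological variability (log-normal jitter on ADC, Tofts rates, T2w mean and
heterogeneity; uniform ±10% region-size jitter), and clinical covariates
drawn from the registry's marginal distributions. PSA follow-up series are
generated consistently with each BCR label so `derive_bcr()` can be
validated against the direct labels. All randomness flows from one master
seed through per-patient counter-derived substreams, so regeneration is
bit-identical and adding a patient never perturbs earlier ones.

**Injected effects.** `effect_contrast()` entries shift tissue parameters in
the poor-outcome group of an endpoint: heterogeneity (structured +
unstructured T2w variability), T2w mean, ADC, $K^{trans}$, $k_{ep}$ or
region size. The defaults encode the qualitative pattern the analysis is
designed to detect — higher texture heterogeneity and lower ADC with worse
outcome, smaller gland with BCR — at magnitudes (+50% PZ heterogeneity for
risk; −15% CZ+TZ ADC, +40% vesicle heterogeneity, −8% PZ size for BCR)
chosen once to make the contrasts clearly detectable at desk-scale cohort
sizes; at small $n$ the region carrying an ADC contrast can saturate its
AUC, and no claim is made that the printed performance matches any
particular real-cohort value.
BCR labels are drawn independently of risk group; no dose–response between
effect size and the printed performance values is claimed.

**What the phantom does not emulate:** real zonal anatomy (ellipsoids, not
anatomical meshes), MRI physics (no k-space, no coil profiles, no
registration error between sequences), ADT-induced signal change, and any
correlation between clinical covariates and imaging beyond the injected
effects. Passing recovery and localization tests therefore demonstrates the
pipeline's correctness and calibration, not clinical performance on real
cohorts.

## Numerical choices and degenerate inputs

* Percentiles: linear interpolation (type 7) everywhere; SD is sample
  ($n-1$) for ROI statistics, population for first-order moments — each
  documented at its definition.
* Tofts bounds and the $v_e \le 1.2$ sanity cap are configurable; voxels at
  bounds or beyond the cap are invalid, and invalid voxels never enter ROI
  statistics.
* Constant ROIs: single gray level; entropy 0, uniformity 1,
  skewness/kurtosis 0; NGTDM coarseness capped at $10^6$.
* Zero-variance features are pruned before correlation screening; constant
  model candidates are dropped as intercept-aliased (infinite VIF).
* AIC ties during backward selection remove the later-ordered variable;
  fold assignment is recorded in every report.

## Problem sizes used by the test-suite and acceptance script

Simulation sizes are chosen to exercise every code path at desk scale:
phantoms of 12–20 voxels per axis, recovery studies over 20 seeds (ADC) and
100 curves (Tofts), texture oracles over 100 random small ROIs, screen
calibration over 1000 null feature tables, null-model AUC over 50 seeds,
effect localization over 25 cohorts of 20 patients, and a 20-case
end-to-end determinism run. The statistical properties they verify
(calibration, localization, convexity, determinism) are size-stable.
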