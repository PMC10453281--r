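Package: radzone
Title: Region-Wise Prostate MRI Imaging-Biomarker Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative imaging-biomarker analysis of multiparametric
    prostate MRI by anatomical region (central+transitional zone, peripheral
    zone, seminal vesicles). Fits apparent diffusion coefficient (ADC) maps
    from multi-b diffusion-weighted series, voxel-wise simplified Tofts
    pharmacokinetic parameters (Ktrans, kep, ve) from dynamic
    contrast-enhanced series, and extracts a 105-feature radiomic set
    (first-order, shape, GLCM, GLRLM, GLSZM, NGTDM, GLDM) per region from
    T2-weighted volumes. Region values are combined into whole-gland
    biomarkers by volume weighting. Includes endpoint derivation (two-group
    risk mapping, PHOENIX biochemical recurrence), univariate screening with
    correlation pruning and normality-driven test selection, and multivariate
    logistic modelling with VIF filtering, AIC backward selection and
    stratified 5-fold cross-validation. A seeded synthetic phantom cohort
    generator with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    minpack.lm,
    pROC,
    car,
    igraph,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
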