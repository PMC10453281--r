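#' Phantom configuration
#'
#' Configuration for a single synthetic multiparametric prostate MRI case.
#' The phantom holds three disjoint anatomical regions on a common grid --
#' central+transitional zone (`cztz`, label 1), peripheral zone (`pz`,
#' label 2) and seminal vesicles (`sv`, label 3) -- built from nested
#' ellipsoids. Each region carries ground-truth tissue parameters: a
#' T2-weighted texture model (mean, structured heterogeneity, noise), an ADC
#' value driving mono-exponential DWI decay, and Tofts parameters
#' (Ktrans, kep) driving the dynamic contrast-enhanced (DCE) curves.
#'
#' Defaults mirror a 1.5 T prostate protocol: 1.6 mm isotropic voxels,
#' b-values 0/500/1000 s/mm^2, and 50 DCE dynamics at 3 s resolution.
#'
#' @param grid_shape Integer vector of 3 grid dimensions.
#' @param voxel_spacing Voxel spacing in mm per axis.
#' @param region_geometry Per-region ellipsoid `center`/`radii` in mm; see
#'   [default_region_geometry()]. The peripheral zone is the outer ellipsoid
#'   minus the central gland and vesicles, so regions are disjoint by
#'   construction; an overlap between `cztz` and `sv` is a configuration
#'   error.
#' @param t2w_texture Per-region list with `mean`, `noise_sd`,
#'   `corr_length_mm` (spatial correlation length of the structured
#'   heterogeneity field) and `blob_amplitude` (its standard deviation).
#' @param adc_truth Named per-region ADC in mm^2/s.
#' @param tofts_truth Named per-region `c(ktrans=, kep=)` in 1/min.
#' @param s0 Baseline DWI signal.
#' @param b_values DWI b-values in s/mm^2 (increasing, starting at 0).
#' @param dwi_noise_sd Additive noise sd on DWI magnitude signal.
#' @param s0_dce Baseline DCE signal.
#' @param dce_noise_sd Additive noise sd on DCE signal.
#' @param dce_dynamics Number of DCE dynamics.
#' @param dce_dt_s DCE temporal resolution in seconds.
#' @param conversion_scale Scale of the linear signal-to-concentration
#'   relation used to synthesise DCE signal, `S = S0 (1 + C/scale)`.
#' @param noise_model `"gaussian"` (default) or `"rician"`.
#' @param aif Optional [aif_curve]; default is the population curve.
#' @param seed Integer seed; regeneration with the same config + seed is
#'   bit-identical.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(32L, 32L, 20L),
                           voxel_spacing = c(1.6, 1.6, 1.6),
                           region_geometry = default_region_geometry(grid_shape, voxel_spacing),
                           t2w_texture = default_t2w_texture(),
                           adc_truth = c(cztz = 1.3e-3, pz = 1.7e-3, sv = 2.2e-3),
                           tofts_truth = list(cztz = c(ktrans = 0.25, kep = 0.60),
                                              pz   = c(ktrans = 0.15, kep = 0.40),
                                              sv   = c(ktrans = 0.10, kep = 0.35)),
                           s0 = 1000,
                           b_values = c(0, 500, 1000),
                           dwi_noise_sd = 20,
                           s0_dce = 500,
                           dce_noise_sd = 5,
                           dce_dynamics = 50L,
                           dce_dt_s = 3,
                           conversion_scale = 1,
                           noise_model = c("gaussian", "rician"),
                           aif = NULL,
                           seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 2),
            length(voxel_spacing) == 3, all(voxel_spacing > 0),
            all(adc_truth > 0), s0 > 0, s0_dce > 0,
            dce_dynamics >= 2, dce_dt_s > 0)
  if (b_values[1] != 0 || is.unsorted(b_values, strictly = TRUE))
    stop("b-values must be strictly increasing and start at 0")
  for (r in region_names()) {
    tt <- tofts_truth[[r]]
    if (tt[["kep"]] <= 0 || tt[["ktrans"]] < 0)
      stop("tofts_truth requires ktrans >= 0 and kep > 0")
    ve <- tt[["ktrans"]] / tt[["kep"]]
    if (ve <= 0 || ve > 1)
      stop(sprintf("implied v_e for region '%s' is %.3f, outside (0, 1]", r, ve))
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_spacing = as.numeric(voxel_spacing),
                 region_geometry = region_geometry,
                 t2w_texture = t2w_texture,
                 adc_truth = adc_truth,
                 tofts_truth = tofts_truth,
                 s0 = s0, b_values = b_values, dwi_noise_sd = dwi_noise_sd,
                 s0_dce = s0_dce, dce_noise_sd = dce_noise_sd,
                 dce_dynamics = as.integer(dce_dynamics), dce_dt_s = dce_dt_s,
                 conversion_scale = conversion_scale,
                 noise_model = noise_model,
                 aif = aif, seed = as.integer(seed)),
            class = "phantom_config")
}

#' @export
region_names <- function() c("cztz", "pz", "sv")

#' @rdname phantom_config
#' @details Region geometry defaults are expressed as fractions of the field
#'   of view so that the same anatomy-like layout fits any grid: a central
#'   gland ellipsoid, a larger outer ellipsoid whose remainder forms the
#'   peripheral zone, and a posterior seminal-vesicle ellipsoid.
#' @export
default_region_geometry <- function(grid_shape, voxel_spacing) {
  fov <- grid_shape * voxel_spacing
  geo <- function(center_f, radii_f) list(center = center_f * fov, radii = radii_f * fov)
  list(cztz     = geo(c(0.50, 0.45, 0.50), c(0.20, 0.16, 0.22)),
       pz_outer = geo(c(0.50, 0.52, 0.50), c(0.28, 0.24, 0.30)),
       sv       = geo(c(0.50, 0.80, 0.58), c(0.16, 0.10, 0.13)))
}

default_t2w_texture <- function() {
  one <- function(mean) list(mean = mean, noise_sd = 40,
                             corr_length_mm = 3, blob_amplitude = 60)
  list(cztz = one(400), pz = one(550), sv = one(700))
}

ellipsoid_mask <- function(grid_shape, spacing, center, radii) {
  cx <- (seq_len(grid_shape[1]) - 0.5) * spacing[1]
  cy <- (seq_len(grid_shape[2]) - 0.5) * spacing[2]
  cz <- (seq_len(grid_shape[3]) - 0.5) * spacing[3]
  dx2 <- ((cx - center[1]) / radii[1])^2
  dy2 <- ((cy - center[2]) / radii[2])^2
  dz2 <- ((cz - center[3]) / radii[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

#' Build the 3-region label map for a phantom configuration
#'
#' @param config A [phantom_config].
#' @return Integer array with codes 0 background, 1 CZ+TZ, 2 PZ, 3 seminal
#'   vesicles.
#' @export
phantom_label_map <- function(config) {
  g <- config$region_geometry
  m_cztz <- ellipsoid_mask(config$grid_shape, config$voxel_spacing,
                           g$cztz$center, g$cztz$radii)
  m_outer <- ellipsoid_mask(config$grid_shape, config$voxel_spacing,
                            g$pz_outer$center, g$pz_outer$radii)
  m_sv <- ellipsoid_mask(config$grid_shape, config$voxel_spacing,
                         g$sv$center, g$sv$radii)
  if (any(m_cztz & m_sv))
    stop("configuration error: cztz and sv ellipsoids overlap")
  lab <- array(0L, config$grid_shape)
  lab[m_outer] <- 2L
  lab[m_cztz] <- 1L
  lab[m_sv] <- 3L
  counts <- tabulate(lab, nbins = 3L)
  if (any(counts == 0L))
    stop("configuration error: empty region(s): ",
         paste(region_names()[counts == 0L], collapse = ", "))
  lab
}

add_noise <- function(x, sd, model) {
  if (sd <= 0) return(x)
  if (model == "rician") {
    sqrt((x + stats::rnorm(length(x), 0, sd))^2 + stats::rnorm(length(x), 0, sd)^2)
  } else {
    x + stats::rnorm(length(x), 0, sd)
  }
}

#' Generate one synthetic phantom case
#'
#' Renders a complete synthetic patient from a [phantom_config]: label map,
#' textured T2-weighted volume, multi-b DWI stack following the
#' mono-exponential decay of each region's true ADC, and a DCE series whose
#' voxel curves follow the simplified Tofts model of each region's true
#' (Ktrans, kep), converted to signal through the same linear enhancement
#' relation the analysis inverts. All randomness is governed by the config
#' seed; the same config generates bit-identical volumes.
#'
#' @param config A [phantom_config].
#' @return An object of class `phantom_case`: a list with `label_map`, `t2w`,
#'   `dwi` (list of `b_values` and 4D `signal`), `dce` (list of `times_s`,
#'   4D `signal`, `aif`, `n_baseline`), `spacing`, `truth` (per-region ADC,
#'   Ktrans, kep, ve) and `clinical` (filled by [generate_cohort()]).
#' @examples
#' case <- generate_phantom(phantom_config(grid_shape = c(16, 16, 8), seed = 7))
#' table(case$label_map)
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  lab <- phantom_label_map(config)
  dm <- config$grid_shape
  sp <- config$voxel_spacing

  # T2w: region mean + structured heterogeneity (smoothed Gaussian field,
  # unit-sd, scaled by blob_amplitude) + white noise.
  t2w <- array(0, dm)
  for (ri in seq_along(region_names())) {
    r <- region_names()[ri]
    tex <- config$t2w_texture[[r]]
    in_r <- lab == ri
    field <- array(stats::rnorm(prod(dm)), dm)
    sigma_vox <- tex$corr_length_mm / sp
    field <- gauss_smooth3d(field, sigma_vox)
    sdf <- stats::sd(field)
    if (sdf > 0) field <- field / sdf
    t2w[in_r] <- tex$mean + tex$blob_amplitude * field[in_r] +
      stats::rnorm(sum(in_r), 0, tex$noise_sd)
  }

  # DWI: S(b) = S0 exp(-b ADC_region) + noise; background stays 0.
  nb <- length(config$b_values)
  dwi <- array(0, c(dm, nb))
  for (bi in seq_len(nb)) {
    vol <- array(0, dm)
    for (ri in seq_along(region_names())) {
      r <- region_names()[ri]
      vol[lab == ri] <- forward_dwi(config$s0, config$adc_truth[[r]],
                                    config$b_values[bi])
    }
    vol[lab > 0] <- add_noise(vol[lab > 0], config$dwi_noise_sd, config$noise_model)
    dwi[, , , bi] <- vol
  }

  # DCE: region Tofts curves -> linear enhancement signal + noise.
  times_s <- (seq_len(config$dce_dynamics) - 1) * config$dce_dt_s
  times_min <- times_s / 60
  aif <- config$aif %||% population_aif(times_min)
  nt <- length(times_s)
  dce <- array(0, c(dm, nt))
  region_ct <- lapply(region_names(), function(r) {
    tt <- config$tofts_truth[[r]]
    forward_tofts(tt[["ktrans"]], tt[["kep"]], aif, times_min)
  })
  for (ti in seq_len(nt)) {
    vol <- array(0, dm)
    for (ri in seq_along(region_names()))
      vol[lab == ri] <- config$s0_dce *
        (1 + region_ct[[ri]][ti] / config$conversion_scale)
    vol[lab > 0] <- add_noise(vol[lab > 0], config$dce_noise_sd, config$noise_model)
    dce[, , , ti] <- vol
  }

  truth <- data.frame(
    region = region_names(),
    adc = as.numeric(config$adc_truth[region_names()]),
    ktrans = vapply(region_names(), function(r) config$tofts_truth[[r]][["ktrans"]], 1),
    kep = vapply(region_names(), function(r) config$tofts_truth[[r]][["kep"]], 1),
    row.names = NULL)
  truth$ve <- truth$ktrans / truth$kep

  structure(list(label_map = lab,
                 t2w = t2w,
                 dwi = list(b_values = config$b_values, signal = dwi),
                 dce = list(times_s = times_s, signal = dce, aif = aif,
                            n_baseline = 1L),
                 spacing = sp,
                 truth = truth,
                 clinical = NULL,
                 config = config),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> grid %s, spacing %s mm\n",
              paste(dim(x$label_map), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x")))
  cat("  regions:", paste(sprintf("%s=%d", region_names(),
                                  tabulate(x$label_map, 3)), collapse = ", "), "\n")
  cat(sprintf("  dwi: %s; dce: %s\n",
              if (is.null(x$dwi)) "absent" else paste(length(x$dwi$b_values), "b-values"),
              if (is.null(x$dce)) "absent" else paste(length(x$dce$times_s), "dynamics")))
  invisible(x)
}
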