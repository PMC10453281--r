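# Case- and cohort-level feature extraction: assembles the patients x
# features table consumed by the statistical analysis.

#' Extract all imaging features for one case
#'
#' Runs the full biomarker extraction on a single (phantom or loaded) case:
#' the 105 radiomic features per region from the T2w volume, the 5 ADC ROI
#' statistics from DWI (if present), the 15 Tofts ROI statistics from DCE
#' (if present), and the whole-gland aggregation (volume-weighted average
#' for non-shape features, shape on the union mask). Features for absent
#' sequences are returned as `NA`.
#'
#' @param case A `phantom_case` (or a case read by [read_case()]).
#' @param n_levels Gray levels for texture discretisation.
#' @param tofts_method Map-fitting method passed to [fit_tofts_map()].
#' @param shape_mode Whole-gland shape aggregation mode.
#' @return Named numeric vector with `region__family__name` entries for the
#'   four regions (`cztz`, `pz`, `sv`, `whole`).
#' @export
extract_case_features <- function(case, n_levels = 32L,
                                  tofts_method = "linear",
                                  shape_mode = "union") {
  lab <- case$label_map
  sp <- case$spacing
  adc_map <- if (!is.null(case$dwi)) fit_adc(case) else NULL
  tofts_maps <- if (!is.null(case$dce))
    fit_tofts_map(case, method = tofts_method) else NULL

  per_region <- list()
  for (ri in seq_along(region_names())) {
    r <- region_names()[ri]
    tex <- extract_texture_features(case$t2w, lab == ri, sp,
                                    n_levels = n_levels)
    adc_names <- paste0("diffusion__ADC_",
                        c("mean", "std", "median", "p25", "p75"))
    if (!is.null(adc_map)) {
      st <- roi_statistics(adc_map, lab, ri)
      adc <- stats::setNames(c(st$mean, st$std, st$median, st$p25, st$p75),
                             adc_names)
    } else {
      adc <- stats::setNames(rep(NA_real_, 5), adc_names)
    }
    if (!is.null(tofts_maps)) {
      pf <- perfusion_roi_features(tofts_maps, lab, ri)
      names(pf) <- paste0("perfusion__", names(pf))
    } else {
      pf <- perfusion_roi_features_names()
    }
    per_region[[r]] <- c(tex, adc, pf)
  }

  w <- roi_weights(lab, sp)
  whole_nonshape <- weighted_average(per_region, w)
  whole_shape <- aggregate_shape(lab, sp, shape_mode = shape_mode,
                                 region_features = per_region)
  # keep manifest order: shape first, then the remaining features
  whole <- c(whole_shape, whole_nonshape)

  out <- c()
  for (r in region_names()) {
    v <- per_region[[r]]
    names(v) <- paste0(r, "__", names(v))
    out <- c(out, v)
  }
  names(whole) <- paste0("whole__", names(whole))
  c(out, whole)
}

perfusion_roi_features_names <- function() {
  nm <- unlist(lapply(c("Ktrans", "kep", "ve"), function(p)
    paste0(p, "_", c("mean", "std", "median", "p25", "p75"))))
  stats::setNames(rep(NA_real_, 15), paste0("perfusion__", nm))
}

#' Build the cohort feature table
#'
#' Applies [extract_case_features()] to every case of a cohort and binds
#' the rows into a patients x features data frame.
#'
#' @param cohort A `phantom_cohort` (or list of cases).
#' @param ... Passed to [extract_case_features()].
#' @return Data frame with `patient_id` plus one column per feature.
#' @export
build_feature_table <- function(cohort, ...) {
  cases <- if (inherits(cohort, "phantom_cohort")) cohort$cases else cohort
  rows <- lapply(cases, function(cs) {
    v <- extract_case_features(cs, ...)
    cbind(data.frame(patient_id = cs$patient_id %||% NA_character_),
          as.data.frame(as.list(v), check.names = FALSE))
  })
  nm <- names(rows[[1]])
  for (r in rows) stopifnot(identical(names(r), nm))
  do.call(rbind, rows)
}
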