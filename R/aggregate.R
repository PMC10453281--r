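#' Region volume weights
#'
#' Volume fraction of each of the three regions:
#' `weight_r = volume_r / (volume_cztz + volume_pz + volume_sv)`.
#'
#' @param label_map Integer label array (1 CZ+TZ, 2 PZ, 3 SV).
#' @param spacing Voxel spacing in mm.
#' @return An object of class `region_weights`: list with `weights` and
#'   `volumes` (mm^3), both named by region.
#' @examples
#' lab <- array(rep(1:3, c(10, 30, 60)), c(10, 10, 1))
#' roi_weights(lab, c(1, 1, 1))$weights
#' @export
roi_weights <- function(label_map, spacing) {
  counts <- tabulate(label_map, nbins = 3L)
  if (any(counts == 0L))
    stop("empty region(s): ", paste(region_names()[counts == 0L], collapse = ", "))
  vols <- counts * prod(spacing)
  names(vols) <- region_names()
  structure(list(weights = vols / sum(vols), volumes = vols),
            class = "region_weights")
}

#' Volume-weighted whole-gland feature aggregation
#'
#' Combines region-level feature values into a whole-prostate value by the
#' volume-weighted average `F_whole = sum_r weight_r * F_r`. Shape features
#' are excluded from weighting: they are instead recomputed on the union of
#' the three region masks (`union_shape`; a per-region sum alternative is
#' available via `shape_mode = "sum"`). A missing regional value (e.g. a
#' patient without DCE) propagates missingness to the whole-gland value.
#'
#' @param region_features Named list (`cztz`, `pz`, `sv`) of named feature
#'   vectors; shape features (names starting `shape__`) are ignored here.
#' @param weights A [roi_weights()] result.
#' @return Named vector of whole-gland values for all non-shape features.
#' @export
weighted_average <- function(region_features, weights) {
  stopifnot(inherits(weights, "region_weights"),
            setequal(names(region_features), region_names()))
  nm <- names(region_features[[region_names()[1]]])
  nm <- nm[!startsWith(nm, "shape__")]
  for (r in region_names()) {
    nr <- names(region_features[[r]])
    nr <- nr[!startsWith(nr, "shape__")]
    if (!identical(sort(nm), sort(nr)))
      stop("regions carry different non-shape feature names")
  }
  out <- stats::setNames(numeric(length(nm)), nm)
  for (f in nm)
    out[f] <- sum(vapply(region_names(),
                         function(r) weights$weights[[r]] * region_features[[r]][[f]],
                         1))
  out
}

#' @rdname weighted_average
#' @param label_map,spacing Label map and spacing for the union-mask shape
#'   computation.
#' @param shape_mode `"union"` (shape on the union mask, default) or
#'   `"sum"` (sum of per-region shape values).
#' @export
aggregate_shape <- function(label_map, spacing,
                            shape_mode = c("union", "sum"),
                            region_features = NULL) {
  shape_mode <- match.arg(shape_mode)
  if (shape_mode == "union") {
    sf <- shape_features(label_map > 0, spacing)
    stats::setNames(as.numeric(sf), paste0("shape__", names(sf)))
  } else {
    nm <- grep("^shape__", names(region_features[[1]]), value = TRUE)
    out <- stats::setNames(numeric(length(nm)), nm)
    for (f in nm)
      out[f] <- sum(vapply(region_names(),
                           function(r) region_features[[r]][[f]], 1))
    out
  }
}
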