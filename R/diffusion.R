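#' Voxel-wise ADC fitting from multi-b DWI
#'
#' Fits the apparent diffusion coefficient per voxel under the Gaussian
#' mono-exponential model `S(b) = S0 exp(-b ADC)` by ordinary least squares
#' of `log S` against `b` (slope = -ADC). The log-linear fit is exact on
#' noiseless exponentials and deterministic. Voxels with any non-positive
#' signal are marked invalid; negative slopes arising from the noise floor
#' are reported as ADC = 0 (and remain valid).
#'
#' @param dwi 4D array `[x, y, z, b]` of DWI signal, or a `phantom_case`
#'   (its `dwi` component is used).
#' @param b_values Numeric vector of b-values in s/mm^2 (>= 2 distinct
#'   values). Taken from the case when `dwi` is a `phantom_case`.
#' @param mask Logical/integer array of voxels to fit; default: label > 0
#'   for a case, all voxels otherwise.
#' @return A `parameter_map`: list with `values` (3D array, mm^2/s),
#'   `units`, and `valid` (logical array of fit success).
#' @examples
#' case <- generate_phantom(phantom_config(grid_shape = c(12, 12, 6),
#'                                         dwi_noise_sd = 0))
#' adc <- fit_adc(case)
#' range(adc$values[adc$valid])
#' @export
fit_adc <- function(dwi, b_values = NULL, mask = NULL) {
  if (inherits(dwi, "phantom_case")) {
    if (is.null(dwi$dwi)) stop("case has no DWI sequence")
    if (is.null(mask)) mask <- dwi$label_map > 0
    b_values <- dwi$dwi$b_values
    dwi <- dwi$dwi$signal
  }
  stopifnot(length(dim(dwi)) == 4)
  if (length(unique(b_values)) < 2)
    stop("ADC fitting requires at least 2 distinct b-values")
  dm <- dim(dwi)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dm)
  mask <- array(as.logical(mask), dm)
  if (!any(mask)) stop("empty mask")

  nb <- length(b_values)
  sig <- matrix(dwi, ncol = nb)[mask, , drop = FALSE]
  ok <- rowSums(sig <= 0) == 0
  vals <- rep(NA_real_, nrow(sig))
  if (any(ok)) {
    ls <- log(sig[ok, , drop = FALSE])
    bc <- b_values - mean(b_values)
    slope <- (ls %*% bc) / sum(bc^2)
    vals[ok] <- pmax(0, -slope)
  }
  values <- array(NA_real_, dm)
  valid <- array(FALSE, dm)
  values[mask] <- vals
  valid[mask] <- ok
  parameter_map(values, "mm^2/s", valid)
}

#' Quantitative parameter map
#'
#' Container for a voxel-wise quantitative map (ADC or a Tofts parameter)
#' with units and a validity mask. Invalid voxels are excluded from all ROI
#' statistics.
#'
#' @param values 3D numeric array.
#' @param units Unit string (`"mm^2/s"`, `"1/min"`, or `""`).
#' @param valid Logical array of the same shape.
#' @export
parameter_map <- function(values, units, valid = !is.na(values)) {
  stopifnot(length(dim(values)) == 3, all(dim(values) == dim(valid)))
  structure(list(values = values, units = units, valid = valid),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  v <- x$values[x$valid]
  cat(sprintf("<parameter_map> %s, %d valid voxels, median %.4g %s\n",
              paste(dim(x$values), collapse = "x"), sum(x$valid),
              if (length(v)) stats::median(v) else NA, x$units))
  invisible(x)
}

#' ROI summary statistics of a parameter map
#'
#' The five ROI statistics used for every quantitative map: mean, standard
#' deviation (sample, n-1), median, and the 25th and 75th percentiles
#' (linear interpolation between order statistics). Only valid voxels enter.
#' An empty valid region yields all-`NA` statistics (a flagged missing
#' value), not an error.
#'
#' @param map A [parameter_map].
#' @param label_map Integer label array on the same grid.
#' @param region_code Integer region code to summarise.
#' @return Named list: `mean`, `std`, `median`, `p25`, `p75`, `n_voxels`.
#' @examples
#' m <- parameter_map(array(1:24, c(2, 3, 4)), "")
#' roi_statistics(m, array(1L, c(2, 3, 4)), 1L)
#' @export
roi_statistics <- function(map, label_map, region_code) {
  stopifnot(inherits(map, "parameter_map"),
            all(dim(label_map) == dim(map$values)))
  sel <- (label_map == region_code) & map$valid
  v <- map$values[sel]
  if (length(v) == 0)
    return(list(mean = NA_real_, std = NA_real_, median = NA_real_,
                p25 = NA_real_, p75 = NA_real_, n_voxels = 0L))
  list(mean = mean(v),
       std = if (length(v) > 1) stats::sd(v) else 0,
       median = q_lin(v, 0.5),
       p25 = q_lin(v, 0.25),
       p75 = q_lin(v, 0.75),
       n_voxels = length(v))
}
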