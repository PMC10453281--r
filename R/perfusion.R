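#' Convert DCE signal to a contrast-concentration curve
#'
#' Default linear relative-enhancement conversion:
#' `C(t) = (S(t) - S0bar) / S0bar * scale`, where `S0bar` is the mean of the
#' first `n_baseline` pre-contrast dynamics. Absolute T1-based conversion is
#' acquisition-specific; this proxy preserves the curve shape that drives
#' the pharmacokinetic fit, and alternative conversions can be plugged in
#' through `fun`.
#'
#' @param signal Numeric vector (one voxel over time) or matrix
#'   `voxels x time`.
#' @param n_baseline Number of pre-contrast dynamics (>= 1).
#' @param scale Proportionality constant of the linear model.
#' @param fun Optional replacement conversion, `function(signal_matrix,
#'   n_baseline)` returning a matrix of concentrations.
#' @return Same shape as `signal`; rows with non-positive baseline are all
#'   `NA` (invalid voxel).
#' @export
signal_to_concentration <- function(signal, n_baseline = 1L, scale = 1,
                                    fun = NULL) {
  vec <- is.null(dim(signal))
  s <- if (vec) matrix(signal, nrow = 1) else as.matrix(signal)
  stopifnot(n_baseline >= 1, n_baseline < ncol(s))
  if (!is.null(fun)) {
    ct <- fun(s, n_baseline)
  } else {
    s0 <- rowMeans(s[, seq_len(n_baseline), drop = FALSE])
    ct <- (s - s0) / s0 * scale
    ct[s0 <= 0, ] <- NA_real_
  }
  if (vec) drop(ct) else ct
}

#' Fit the simplified Tofts model to one concentration curve
#'
#' Bounded nonlinear least squares of `Ct(t)` against [forward_tofts()],
#' minimising the residual sum of squares over `ktrans` in [0, 5] 1/min and
#' `kep` in (0, 10] 1/min. The optimiser is started from a 3-point grid of
#' (ktrans, kep) initial values and the best converged fit is kept.
#' `ve = ktrans / kep` is derived, never fitted independently.
#'
#' @param ct Concentration curve (>= 10 time points).
#' @param aif An [aif_curve] covering `times`.
#' @param times Sample times in minutes.
#' @param init Matrix of starting values (rows of `c(ktrans, kep)`);
#'   default 3-start grid.
#' @param bounds List with `ktrans = c(lo, hi)`, `kep = c(lo, hi)`.
#' @return A `tofts_fit`: list with `ktrans`, `kep`, `ve`, `fit_rss`,
#'   `converged`, and `at_bound`.
#' @examples
#' t <- seq(0, 2.45, by = 0.05)
#' aif <- population_aif(t)
#' fit <- fit_tofts(forward_tofts(0.25, 0.5, aif, t), aif, t)
#' c(fit$ktrans, fit$kep, fit$ve)
#' @export
fit_tofts <- function(ct, aif, times,
                      init = default_tofts_init(),
                      bounds = list(ktrans = c(0, 5), kep = c(1e-3, 10))) {
  stopifnot(length(ct) == length(times), length(times) >= 10)
  if (all(!is.finite(ct)))
    return(tofts_fit(NA, NA, NA, converged = FALSE))
  ca <- resample_aif(aif, times)
  aif_grid <- aif_curve(times, ca, source = aif$source)
  if (max(abs(ct), na.rm = TRUE) < .Machine$double.eps^0.5) {
    # Identically zero curve: ktrans 0, kep unidentifiable (left at bound).
    return(tofts_fit(0, bounds$kep[1], 0, rss = 0,
                     converged = TRUE, at_bound = TRUE))
  }
  best <- NULL
  for (i in seq_len(nrow(init))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        ct ~ forward_tofts(ktrans, kep, aif_grid, times),
        start = list(ktrans = unname(init[i, 1]), kep = unname(init[i, 2])),
        lower = c(bounds$ktrans[1], bounds$kep[1]),
        upper = c(bounds$ktrans[2], bounds$kep[2]),
        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(coef = stats::coef(fit), rss = rss)
  }
  if (is.null(best)) return(tofts_fit(NA, NA, NA, converged = FALSE))
  kt <- unname(best$coef[[1]]); ke <- unname(best$coef[[2]])
  at_bound <- kt >= bounds$ktrans[2] - 1e-9 || ke <= bounds$kep[1] + 1e-9 ||
    ke >= bounds$kep[2] - 1e-9
  tofts_fit(kt, ke, kt / ke, rss = best$rss, converged = TRUE,
            at_bound = at_bound)
}

default_tofts_init <- function() {
  matrix(c(0.05, 0.3,
           0.20, 1.0,
           1.00, 3.0), ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("ktrans", "kep")))
}

tofts_fit <- function(ktrans, kep, ve, rss = NA_real_, converged = FALSE,
                      at_bound = FALSE) {
  structure(list(ktrans = ktrans, kep = kep, ve = ve, fit_rss = rss,
                 converged = converged, at_bound = at_bound),
            class = "tofts_fit")
}

#' Voxel-wise simplified Tofts parameter maps
#'
#' Fits Ktrans and kep in every masked voxel of a DCE series. The default
#' `"linear"` method solves the integral form of the model,
#' `Ct(t) = Ktrans int C_AIF - kep int Ct`, by linear least squares with
#' cumulative trapezoidal integrals -- fully vectorised across voxels, and
#' consistent with the piecewise-linear AIF convention of [forward_tofts()].
#' `method = "nls"` refines every voxel with [fit_tofts()]. Voxels with
#' non-physical results (`ktrans < 0`, `kep <= 0`, or `ve` above
#' `ve_max`) are marked invalid.
#'
#' @param case A `phantom_case` with a DCE series, or a 4D array.
#' @param times_s Acquisition times in seconds (when `case` is an array).
#' @param aif An [aif_curve] (times in minutes).
#' @param mask Voxels to fit; defaults to label > 0 for a case.
#' @param n_baseline Pre-contrast dynamics for signal conversion.
#' @param conversion_scale Scale of the linear signal conversion.
#' @param method `"linear"` or `"nls"`.
#' @param ve_max Upper sanity bound on `ve`; above it the voxel is invalid.
#' @return List of three [parameter_map]s: `ktrans`, `kep` (1/min) and `ve`
#'   (dimensionless, `ve = ktrans/kep` at machine precision).
#' @export
fit_tofts_map <- function(case, times_s = NULL, aif = NULL, mask = NULL,
                          n_baseline = 1L, conversion_scale = 1,
                          method = c("linear", "nls"), ve_max = 1.2) {
  method <- match.arg(method)
  if (inherits(case, "phantom_case")) {
    if (is.null(case$dce)) stop("case has no DCE sequence")
    if (is.null(mask)) mask <- case$label_map > 0
    times_s <- case$dce$times_s
    aif <- aif %||% case$dce$aif
    n_baseline <- case$dce$n_baseline %||% 1L
    conversion_scale <- case$config$conversion_scale %||% conversion_scale
    dce <- case$dce$signal
  } else {
    dce <- case
  }
  stopifnot(length(dim(dce)) == 4, !is.null(times_s), !is.null(aif))
  dm <- dim(dce)[1:3]
  nt <- dim(dce)[4]
  if (is.null(mask)) mask <- array(TRUE, dm)
  mask <- array(as.logical(mask), dm)
  times <- times_s / 60
  ca <- resample_aif(aif, times)

  sig <- matrix(dce, ncol = nt)[mask, , drop = FALSE]
  ct <- signal_to_concentration(sig, n_baseline, conversion_scale)
  nvox <- nrow(ct)
  kt <- rep(NA_real_, nvox); ke <- rep(NA_real_, nvox)

  if (method == "linear") {
    # Per-voxel 2x2 normal equations of Ct ~ ktrans A1 - kep A2.
    a1 <- cumtrapz1(times, ca)
    dtm <- diff(times)
    # cumulative trapezoid of each voxel's ct
    inc <- (ct[, -1, drop = FALSE] + ct[, -nt, drop = FALSE]) / 2 *
      rep(dtm, each = nvox)
    a2 <- cbind(0, t(apply(inc, 1, cumsum)))
    s11 <- sum(a1^2)
    s12 <- -rowSums(a2 * rep(a1, each = nvox))
    s22 <- rowSums(a2^2)
    b1 <- rowSums(ct * rep(a1, each = nvox))
    b2 <- -rowSums(ct * a2)
    det <- s11 * s22 - s12^2
    ok <- is.finite(det) & det > 1e-12 * (s11 + s22 + 1e-300)^2 &
      rowSums(!is.finite(ct)) == 0
    kt[ok] <- (s22[ok] * b1[ok] - s12[ok] * b2[ok]) / det[ok]
    ke[ok] <- (-s12[ok] * b1[ok] + s11 * b2[ok]) / det[ok]
  } else {
    aifr <- aif_curve(times, ca, source = aif$source)
    for (i in seq_len(nvox)) {
      if (any(!is.finite(ct[i, ]))) next
      f <- fit_tofts(ct[i, ], aifr, times)
      if (f$converged) { kt[i] <- f$ktrans; ke[i] <- f$kep }
    }
  }

  ve <- kt / ke
  bad <- !is.finite(kt) | !is.finite(ke) | kt < 0 | ke <= 0 | ve > ve_max
  kt[bad] <- NA_real_; ke[bad] <- NA_real_; ve[bad] <- NA_real_

  put <- function(v, units) {
    arr <- array(NA_real_, dm); arr[mask] <- v
    val <- array(FALSE, dm); val[mask] <- !is.na(v)
    parameter_map(arr, units, val)
  }
  list(ktrans = put(kt, "1/min"), kep = put(ke, "1/min"), ve = put(ve, ""))
}

#' The 15 perfusion ROI features
#'
#' Applies [roi_statistics()] to each of the Ktrans, kep and ve maps,
#' yielding mean, std, median, p25 and p75 per map (5 x 3 = 15 features).
#'
#' @param maps List of parameter maps as returned by [fit_tofts_map()].
#' @param label_map Integer label array.
#' @param region_code Region to summarise.
#' @return Named numeric vector of 15 features (`Ktrans_mean` ... `ve_p75`).
#' @export
perfusion_roi_features <- function(maps, label_map, region_code) {
  out <- c()
  pretty <- c(ktrans = "Ktrans", kep = "kep", ve = "ve")
  for (nm in c("ktrans", "kep", "ve")) {
    st <- roi_statistics(maps[[nm]], label_map, region_code)
    v <- c(st$mean, st$std, st$median, st$p25, st$p75)
    names(v) <- paste0(pretty[[nm]], "_", c("mean", "std", "median", "p25", "p75"))
    out <- c(out, v)
  }
  out
}
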