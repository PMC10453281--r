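#' Mono-exponential diffusion-weighted signal model
#'
#' Forward model for diffusion-weighted imaging: the Gaussian mono-exponential
#' decay `S(b) = S0 * exp(-b * ADC)`.
#'
#' @param s0 Baseline signal at b = 0 (must be positive).
#' @param adc Apparent diffusion coefficient in mm^2/s (non-negative).
#' @param b_values Diffusion weightings in s/mm^2 (non-negative).
#' @return Numeric vector of signals, one per b-value.
#' @examples
#' forward_dwi(1000, 1.0e-3, c(0, 500, 1000))
#' @export
forward_dwi <- function(s0, adc, b_values) {
  stopifnot(s0 > 0, adc >= 0)
  if (any(b_values < 0)) stop("b-values must be non-negative")
  s0 * exp(-b_values * adc)
}

#' Simplified Tofts forward model
#'
#' Tissue contrast concentration under the one-input two-compartment
#' (simplified Tofts) model,
#' `Ct(t) = Ktrans * integral_0^t C_AIF(tau) * exp(-kep * (t - tau)) dtau`.
#' The convolution is evaluated by an exponential-kernel recursion that is
#' exact when the AIF is treated as piecewise linear between its samples;
#' this convention is shared with the voxel-wise fitting routines.
#'
#' @param ktrans Transfer constant in 1/min (non-negative).
#' @param kep Efflux rate constant in 1/min (positive).
#' @param aif An [aif_curve] covering `times`.
#' @param times Output sample times in minutes (non-negative, increasing).
#' @return Numeric vector `Ct(times)`; `Ct(0) = 0`.
#' @examples
#' t <- seq(0, 2.5, by = 0.05)
#' ct <- forward_tofts(0.25, 0.5, population_aif(t), t)
#' @export
forward_tofts <- function(ktrans, kep, aif, times) {
  stopifnot(ktrans >= 0, kep > 0, all(times >= 0), !is.unsorted(times))
  ca <- resample_aif(aif, times)
  ktrans * exp_conv(ca, kep, times)
}

# Recursion for F(t) = integral_0^t Ca(tau) exp(-kep (t - tau)) dtau with Ca
# piecewise linear on the grid. Exact segment integral:
#   int_{ti}^{ti+1} (a + m (tau - ti)) e^{-kep (ti+1 - tau)} dtau
#     = a (1 - E)/kep + m (dt - (1 - E)/kep)/kep,  E = exp(-kep dt).
exp_conv <- function(ca, kep, times) {
  n <- length(times)
  out <- numeric(n)
  if (n < 2) return(out)
  dt <- diff(times)
  E <- exp(-kep * dt)
  a <- ca[-n]
  m <- (ca[-1] - ca[-n]) / dt
  inc <- a * (1 - E) / kep + m * (dt - (1 - E) / kep) / kep
  for (i in seq_len(n - 1)) out[i + 1] <- E[i] * out[i] + inc[i]
  out
}
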