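#' First-order (histogram) features
#'
#' The 18 intensity-distribution features of the manifest, computed on the
#' raw (continuous) ROI values. `Entropy` and `Uniformity` use the
#' discretised histogram (same binning as the texture matrices). Moments use
#' the population convention (denominator N); skewness and kurtosis of a
#' zero-variance ROI are defined as 0. Kurtosis is not excess-corrected
#' (a normal sample gives about 3).
#'
#' @param values Numeric vector of ROI voxel intensities (>= 1 voxel).
#' @param spacing Voxel spacing in mm (for `TotalEnergy`).
#' @param n_bins Histogram bins for entropy/uniformity.
#' @return Named numeric vector of 18 features.
#' @examples
#' first_order_features(c(1, 2, 3, 4, 5))[c("Mean", "Median", "Skewness")]
#' @export
first_order_features <- function(values, spacing = c(1, 1, 1), n_bins = 32L) {
  x <- values[is.finite(values)]
  stopifnot(length(x) >= 1)
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  p10 <- q_lin(x, 0.10); p90 <- q_lin(x, 0.90)
  p25 <- q_lin(x, 0.25); p75 <- q_lin(x, 0.75)
  mid <- x[x >= p10 & x <= p90]

  # histogram probabilities for entropy / uniformity
  if (max(x) == min(x)) {
    p <- 1
  } else {
    w <- (max(x) - min(x)) / n_bins
    lev <- pmin(floor((x - min(x)) / w) + 1, n_bins)
    p <- tabulate(lev, n_bins) / n
    p <- p[p > 0]
  }

  c(Energy = sum(x^2),
    TotalEnergy = prod(spacing) * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    `10Percentile` = p10,
    `90Percentile` = p90,
    Maximum = max(x),
    Mean = mu,
    Median = q_lin(x, 0.5),
    InterquartileRange = p75 - p25,
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = if (length(mid)) mean(abs(mid - mean(mid))) else 0,
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
}
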