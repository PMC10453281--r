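#' Gray-level discretisation of an ROI
#'
#' Assigns each masked voxel an integer gray level for the texture-matrix
#' families. Default is fixed bin count over the ROI's min--max range
#' (scale-free across intensity ranges); fixed bin width is available as an
#' alternative. The maximum value maps to the top bin. A constant ROI
#' collapses to a single level, which is allowed.
#'
#' @param volume 3D numeric array.
#' @param mask Logical array (same shape); voxels outside are ignored.
#' @param n_levels Number of gray levels for `"fixed-count"` binning.
#' @param binning `"fixed-count"` (default) or `"fixed-width"`.
#' @param bin_width Bin width for `"fixed-width"`.
#' @return An object of class `discretized_roi`: `levels` (integer array
#'   over the ROI bounding box, `NA` outside the mask), `n_levels`
#'   (effective maximum level), `binning`, `mask` (cropped).
#' @examples
#' v <- array(runif(64), c(4, 4, 4))
#' d <- discretize(v, array(TRUE, c(4, 4, 4)), n_levels = 8)
#' range(d$levels)
#' @export
discretize <- function(volume, mask, n_levels = 32L,
                       binning = c("fixed-count", "fixed-width"),
                       bin_width = NULL) {
  binning <- match.arg(binning)
  stopifnot(all(dim(volume) == dim(mask)))
  mask <- array(as.logical(mask), dim(volume))
  if (!any(mask)) stop("empty mask")
  bb <- bounding_box(mask)
  v <- volume[bb$x, bb$y, bb$z, drop = FALSE]
  m <- mask[bb$x, bb$y, bb$z, drop = FALSE]
  dim(v) <- dim(m) <- bb$dim

  x <- v[m]
  lo <- min(x)
  if (binning == "fixed-count") {
    hi <- max(x)
    if (hi == lo) {
      lev_vals <- rep(1L, length(x))
      n_eff <- 1L
    } else {
      w <- (hi - lo) / n_levels
      lev_vals <- pmin(as.integer(floor((x - lo) / w)) + 1L, as.integer(n_levels))
      n_eff <- max(lev_vals)
    }
    param <- as.integer(n_levels)
  } else {
    stopifnot(!is.null(bin_width), bin_width > 0)
    lev_vals <- as.integer(floor((x - lo) / bin_width)) + 1L
    n_eff <- max(lev_vals)
    param <- bin_width
  }
  lev <- array(NA_integer_, dim(m))
  lev[m] <- lev_vals
  structure(list(levels = lev, n_levels = n_eff,
                 binning = list(method = binning, parameter = param),
                 mask = m),
            class = "discretized_roi")
}

bounding_box <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  rng <- apply(idx, 2, range)
  list(x = rng[1, 1]:rng[2, 1], y = rng[1, 2]:rng[2, 2], z = rng[1, 3]:rng[2, 3],
       dim = rng[2, ] - rng[1, ] + 1L)
}
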