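#' The 105-feature radiomic manifest
#'
#' The fixed, ordered list of radiomic features extracted per region:
#' 14 shape + 18 first-order + 22 GLCM + 16 GLRLM + 16 GLSZM + 14 GLDM +
#' 5 NGTDM = 105 features. The same manifest (name and family) is shipped
#' as machine-readable JSON in `inst/extdata/feature_manifest.json`.
#'
#' @return Data frame with columns `family` and `name`, 105 rows, in the
#'   stable extraction order.
#' @examples
#' nrow(feature_manifest())
#' @export
feature_manifest <- function() {
  shape <- c("MeshVolume", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
             "Sphericity", "Maximum3DDiameter", "Maximum2DDiameterSlice",
             "Maximum2DDiameterColumn", "Maximum2DDiameterRow",
             "MajorAxisLength", "MinorAxisLength", "LeastAxisLength",
             "Elongation", "Flatness")
  firstorder <- c("Energy", "TotalEnergy", "Entropy", "Minimum",
                  "10Percentile", "90Percentile", "Maximum", "Mean", "Median",
                  "InterquartileRange", "Range", "MeanAbsoluteDeviation",
                  "RobustMeanAbsoluteDeviation", "RootMeanSquared",
                  "Skewness", "Kurtosis", "Variance", "Uniformity")
  glcm <- c("Autocorrelation", "ClusterProminence", "ClusterShade",
            "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
            "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn",
            "Idn", "Imc1", "Imc2", "InverseVariance", "JointAverage",
            "JointEnergy", "JointEntropy", "MaximumProbability", "SumEntropy",
            "SumSquares")
  rbind(data.frame(family = "shape", name = shape),
        data.frame(family = "firstorder", name = firstorder),
        data.frame(family = "glcm", name = glcm),
        data.frame(family = "glrlm", name = glrlm_names),
        data.frame(family = "glszm", name = glszm_names),
        data.frame(family = "gldm", name = gldm_names),
        data.frame(family = "ngtdm", name = c("Coarseness", "Contrast",
                                              "Busyness", "Complexity",
                                              "Strength")))
}

#' Extract the full 105-feature vector from one ROI
#'
#' Runs every feature family of [feature_manifest()] on a masked region of
#' a scalar volume. Texture matrices use the configured discretisation;
#' first-order features use the raw intensities (with the same binning for
#' entropy/uniformity); shape features use only the mask and spacing.
#'
#' @param volume 3D intensity array (typically T2-weighted).
#' @param mask Logical array selecting the region.
#' @param spacing Voxel spacing in mm.
#' @param n_levels Gray levels for discretisation.
#' @param binning Binning mode passed to [discretize()].
#' @param bin_width Bin width for `"fixed-width"` binning.
#' @return Named numeric vector of 105 features, names `family__name`,
#'   ordered as the manifest.
#' @export
extract_texture_features <- function(volume, mask, spacing = c(1, 1, 1),
                                     n_levels = 32L,
                                     binning = "fixed-count",
                                     bin_width = NULL) {
  d <- discretize(volume, mask, n_levels = n_levels, binning = binning,
                  bin_width = bin_width)
  vals <- volume[array(as.logical(mask), dim(volume))]
  out <- c(shape = shape_features(mask, spacing),
           firstorder = first_order_features(vals, spacing, n_bins = n_levels),
           glcm = glcm_features(d),
           glrlm = glrlm_features(d),
           glszm = glszm_features(d),
           gldm = gldm_features(d),
           ngtdm = ngtdm_features(d))
  names(out) <- sub("\\.", "__", names(out))
  mf <- feature_manifest()
  expected <- paste0(mf$family, "__", mf$name)
  stopifnot(identical(names(out), expected))
  out
}
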