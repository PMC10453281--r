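test_that("the manifest has exactly 105 uniquely named features incl. all published names", {
  mf <- feature_manifest()
  expect_equal(nrow(mf), 105)
  expect_equal(anyDuplicated(paste(mf$family, mf$name)), 0)
  expect_equal(as.integer(table(mf$family)[c("shape", "firstorder", "glcm",
                                             "glrlm", "glszm", "gldm",
                                             "ngtdm")]),
               c(14L, 18L, 22L, 16L, 16L, 14L, 5L))
  required <- list(
    firstorder = c("10Percentile", "Median", "Skewness"),
    shape = c("Flatness", "MajorAxisLength", "MinorAxisLength",
              "Maximum2DDiameterRow", "Maximum2DDiameterColumn",
              "Maximum2DDiameterSlice", "Maximum3DDiameter",
              "SurfaceVolumeRatio"),
    glcm = c("Id", "Idm", "Correlation", "Imc1", "Imc2", "ClusterShade",
             "InverseVariance", "MaximumProbability"),
    glrlm = c("ShortRunEmphasis", "RunVariance"),
    glszm = c("LargeAreaEmphasis", "LargeAreaHighGrayLevelEmphasis",
              "LargeAreaLowGrayLevelEmphasis"),
    gldm = c("DependenceEntropy", "LargeDependenceLowGrayLevelEmphasis"),
    ngtdm = c("Strength", "Complexity"))
  for (fam in names(required))
    expect_true(all(required[[fam]] %in% mf$name[mf$family == fam]),
                label = paste("required", fam, "features present"))
})

test_that("discretisation follows the fixed-count edge rules", {
  v <- array(0:31 + 0.0, c(8, 4, 1))
  d <- discretize(v, array(TRUE, dim(v)), n_levels = 32)
  expect_equal(as.vector(d$levels), floor(0:31) + 1L)  # unit-width bins
  # max value maps to the top bin
  expect_equal(max(d$levels), 32L)
  # constant ROI collapses to a single level
  dc <- discretize(array(5, c(2, 2, 1)), array(TRUE, c(2, 2, 1)))
  expect_equal(unique(as.vector(dc$levels)), 1L)
  expect_equal(dc$n_levels, 1L)
  # monotone transform preserving bin boundaries keeps levels identical
  d2 <- discretize(v * 3 + 10, array(TRUE, dim(v)), n_levels = 32)
  expect_identical(d$levels, d2$levels)
})

test_that("first-order features match hand computations", {
  f <- first_order_features(c(1, 2, 3, 4, 5))
  expect_equal(unname(f["Mean"]), 3)
  expect_equal(unname(f["Median"]), 3)
  expect_equal(unname(f["10Percentile"]),
               unname(quantile(1:5, 0.1, type = 7)))
  expect_equal(unname(f["InterquartileRange"]), 2)
  expect_equal(unname(f["Energy"]), sum((1:5)^2))
  expect_equal(unname(f["Variance"]), mean((1:5 - 3)^2))
  # constant ROI: entropy 0, uniformity 1, skewness 0
  fc <- first_order_features(rep(4, 10))
  expect_equal(unname(fc[c("Entropy", "Uniformity", "Skewness", "Kurtosis")]),
               c(0, 1, 0, 0))
  # two-level half/half: uniformity 1/2, entropy 1 bit
  f2 <- first_order_features(rep(c(0, 10), 8))
  expect_equal(unname(f2["Uniformity"]), 0.5)
  expect_equal(unname(f2["Entropy"]), 1)
})

test_that("shape features match the cube geometry oracle", {
  cube <- array(TRUE, c(10, 10, 10))
  f <- shape_features(cube, c(1, 1, 1))
  expect_equal(unname(f["VoxelVolume"]), 1000)
  expect_equal(unname(f["MeshVolume"]), 1000)
  expect_equal(unname(f["SurfaceArea"]), 600)
  expect_equal(unname(f["SurfaceVolumeRatio"]), 0.6)
  expect_equal(unname(f["Maximum3DDiameter"]), sqrt(300))  # opposite mesh corners
  expect_equal(unname(f["Maximum2DDiameterSlice"]), sqrt(200))
  expect_equal(unname(f["Flatness"]), 1)                   # equal eigenvalues
  expect_equal(unname(f["Elongation"]), 1)
  # spacing equivariance: doubling spacing doubles lengths, halves area/volume ratio
  f2 <- shape_features(cube, c(2, 2, 2))
  expect_equal(unname(f2["MajorAxisLength"]), 2 * unname(f["MajorAxisLength"]))
  expect_equal(unname(f2["SurfaceVolumeRatio"]),
               unname(f["SurfaceVolumeRatio"]) / 2)
  expect_equal(unname(f2["Maximum3DDiameter"]), 2 * unname(f["Maximum3DDiameter"]))
})

test_that("single-voxel masks degrade to voxel dimensions, flagged", {
  m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
  f <- shape_features(m, c(1, 1.5, 2))
  expect_equal(unname(f["VoxelVolume"]), 3)
  expect_equal(unname(f["MajorAxisLength"]), 2)
  expect_equal(unname(f["LeastAxisLength"]), 1)
  expect_true(attr(f, "degenerate"))
})

test_that("GLCM matches closed forms on constant and checkerboard ROIs", {
  # constant ROI
  dcon <- discretize(array(3, c(3, 3, 2)), array(TRUE, c(3, 3, 2)))
  f <- glcm_features(dcon)
  expect_equal(unname(f["MaximumProbability"]), 1)
  expect_equal(unname(f["Id"]), 1)
  expect_equal(unname(f["ClusterShade"]), 0)
  # two-level checkerboard: correlation -1 along in-plane offsets
  v <- array(0, c(4, 4, 1))
  v[] <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  d <- discretize(v, array(TRUE, dim(v)), binning = "fixed-width", bin_width = 1)
  P <- glcm_matrix(d, c(1, 0, 0))
  fo <- radzone:::glcm_features_one(P)
  expect_equal(unname(fo["Correlation"]), -1)
})

test_that("2x2x1 four-level image matches the exhaustive pair-enumeration oracle", {
  v <- array(c(1, 3, 2, 4) + 0.0, c(2, 2, 1))
  d <- discretize(v, array(TRUE, c(2, 2, 1)), binning = "fixed-width",
                  bin_width = 1)
  for (r in seq_len(nrow(radzone:::unique_offsets_3d()))) {
    off <- radzone:::unique_offsets_3d()[r, ]
    expect_equal(glcm_matrix(d, off), bf_glcm(d$levels, off, d$n_levels))
  }
})

test_that("constant line ROI yields a single run: ShortRunEmphasis 1/n^2", {
  n <- 5
  v <- array(2, c(n, 1, 1))
  d <- discretize(v, array(TRUE, c(n, 1, 1)))
  R <- glrlm_matrix(d, c(1L, 0L, 0L))
  expect_equal(dim(R), c(1L, n))
  expect_equal(R[1, n], 1)
  expect_equal(sum(R), 1)
  sre <- sum(R / matrix((1:n)^2, 1, n, byrow = TRUE)) / sum(R)
  expect_equal(sre, 1 / n^2)
})

test_that("constant ROI closed forms: GLSZM LargeAreaEmphasis n^2, NGTDM Complexity 0", {
  v <- array(1, c(3, 3, 2))
  d <- discretize(v, array(TRUE, c(3, 3, 2)))
  n <- 18
  f <- glszm_features(d)
  expect_equal(unname(f["LargeAreaEmphasis"]), n^2)
  expect_equal(unname(ngtdm_features(d)["Complexity"]), 0)
  expect_equal(unname(ngtdm_features(d)["Contrast"]), 0)
})

test_that("all five matrix families equal brute-force enumeration on 100 random ROIs", {
  offs <- radzone:::unique_offsets_3d()
  for (seed in 1:100) {
    d <- random_small_roi(seed)
    L <- d$n_levels
    # one random offset/direction per instance for the directional families
    off <- offs[(seed %% 13) + 1, ]
    expect_equal(glcm_matrix(d, off), bf_glcm(d$levels, off, L),
                 label = paste("glcm seed", seed))
    expect_equal(glrlm_matrix(d, off), bf_glrlm(d$levels, off, L),
                 label = paste("glrlm seed", seed))
    expect_equal(glszm_matrix(d), bf_glszm(d$levels, L),
                 label = paste("glszm seed", seed))
    expect_equal(gldm_matrix(d), bf_gldm(d$levels, L),
                 label = paste("gldm seed", seed))
    nt <- radzone:::ngtdm_table(d)
    bt <- bf_ngtdm(d$levels, L)
    expect_equal(nt$s, bt$s, label = paste("ngtdm s seed", seed))
    expect_equal(nt$n, bt$n, label = paste("ngtdm n seed", seed))
    expect_equal(nt$nvp, bt$nvp, label = paste("ngtdm nvp seed", seed))
  }
})

test_that("feature vector is 105 long, stably ordered, translation invariant", {
  set.seed(5)
  v <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  m <- array(FALSE, c(6, 6, 4)); m[2:4, 2:4, 2:3] <- TRUE
  f1 <- extract_texture_features(v, m, c(1, 1, 1))
  expect_length(f1, 105)
  # translate ROI (and its intensities) by one voxel
  v2 <- array(0, c(6, 6, 4)); m2 <- array(FALSE, c(6, 6, 4))
  v2[3:5, 2:4, 2:3] <- v[2:4, 2:4, 2:3]; m2[3:5, 2:4, 2:3] <- TRUE
  f2 <- extract_texture_features(v2, m2, c(1, 1, 1))
  expect_equal(f1, f2)
  # rerun is bit-identical
  expect_identical(f1, extract_texture_features(v, m, c(1, 1, 1)))
})
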