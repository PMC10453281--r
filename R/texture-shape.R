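#' Shape features of a 3D mask
#'
#' The 14 geometric features of the manifest. The surface mesh is built from
#' the exposed faces of the voxelised mask (vertices at voxel corners):
#' `SurfaceArea` is the summed area of exposed faces, and the mesh encloses
#' exactly the masked voxels, so `MeshVolume` equals `VoxelVolume` under
#' this convention. Diameters are maxima of pairwise distances over surface
#' vertices: `Maximum3DDiameter` over all pairs, and the three 2D diameters
#' over pairs sharing a slice (z), column (y) or row (x) corner plane.
#' Principal axis lengths are `4 * sqrt(eigenvalue)` of the physical voxel
#' centre covariance (sample, n-1); `Elongation = sqrt(l2/l1)` and
#' `Flatness = sqrt(l3/l1)` with eigenvalues sorted decreasingly. A
#' single-voxel mask has degenerate axes, reported as the sorted voxel
#' dimensions and flagged via the `"degenerate"` attribute.
#'
#' @param mask Logical 3D array (non-empty).
#' @param spacing Voxel spacing in mm.
#' @return Named numeric vector of 14 features.
#' @examples
#' cube <- array(TRUE, c(10, 10, 10))
#' shape_features(cube, c(1, 1, 1))[c("VoxelVolume", "SurfaceArea", "Flatness")]
#' @export
shape_features <- function(mask, spacing = c(1, 1, 1)) {
  mask <- array(as.logical(mask), dim(mask))
  n <- sum(mask)
  stopifnot(n >= 1)
  vol <- n * prod(spacing)

  # exposed faces and their corner vertices
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                 spacing[1] * spacing[2])
  area <- 0
  verts <- list()
  mnum <- array(as.numeric(mask), dim(mask))
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      d <- c(0L, 0L, 0L); d[ax] <- s
      nb <- shift_array(mnum, d)
      nb[is.na(nb)] <- 0
      exposed <- mask & nb == 0
      ne <- sum(exposed)
      if (ne == 0) next
      area <- area + ne * face_area[ax]
      idx <- which(exposed, arr.ind = TRUE)
      # face lies on the corner plane idx[ax] - 1 (s = -1) or idx[ax] (s = +1)
      base <- idx - 1L
      base[, ax] <- base[, ax] + (s + 1L) / 2L
      oth <- setdiff(1:3, ax)
      for (d1 in 0:1) for (d2 in 0:1) {
        vv <- base
        vv[, oth[1]] <- vv[, oth[1]] + d1
        vv[, oth[2]] <- vv[, oth[2]] + d2
        verts[[length(verts) + 1]] <- vv
      }
    }
  }
  v <- unique(do.call(rbind, verts))
  pts <- sweep(v, 2, spacing, `*`)

  max3d <- max_pairwise_dist(pts)
  max2d_slice <- max_pairwise_dist_grouped(pts[, 1:2, drop = FALSE], v[, 3])
  max2d_col <- max_pairwise_dist_grouped(pts[, c(1, 3), drop = FALSE], v[, 2])
  max2d_row <- max_pairwise_dist_grouped(pts[, 2:3, drop = FALSE], v[, 1])

  centers <- which(mask, arr.ind = TRUE)
  centers <- sweep(centers - 0.5, 2, spacing, `*`)
  degenerate <- FALSE
  if (n > 1) {
    ev <- sort(pmax(eigen(stats::cov(centers), symmetric = TRUE,
                          only.values = TRUE)$values, 0), decreasing = TRUE)
    if (ev[1] <= 0) degenerate <- TRUE
  } else {
    degenerate <- TRUE
  }
  if (degenerate) {
    sp <- sort(spacing, decreasing = TRUE)
    axes <- sp
    elong <- sp[2] / sp[1]
    flat <- sp[3] / sp[1]
  } else {
    axes <- 4 * sqrt(ev)
    elong <- sqrt(ev[2] / ev[1])
    flat <- sqrt(ev[3] / ev[1])
  }

  out <- c(MeshVolume = vol,
           VoxelVolume = vol,
           SurfaceArea = area,
           SurfaceVolumeRatio = area / vol,
           Sphericity = (36 * pi * vol^2)^(1 / 3) / area,
           Maximum3DDiameter = max3d,
           Maximum2DDiameterSlice = max2d_slice,
           Maximum2DDiameterColumn = max2d_col,
           Maximum2DDiameterRow = max2d_row,
           MajorAxisLength = axes[1],
           MinorAxisLength = axes[2],
           LeastAxisLength = axes[3],
           Elongation = elong,
           Flatness = flat)
  attr(out, "degenerate") <- degenerate
  out
}

max_pairwise_dist <- function(pts) {
  if (nrow(pts) < 2) return(0)
  max(stats::dist(pts))
}

# Largest in-plane distance over vertex pairs sharing the same plane index.
max_pairwise_dist_grouped <- function(pts2, group) {
  m <- 0
  for (g in unique(group)) {
    sel <- group == g
    if (sum(sel) >= 2) m <- max(m, max_pairwise_dist(pts2[sel, , drop = FALSE]))
  }
  m
}
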