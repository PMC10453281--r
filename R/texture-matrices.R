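# Gray-level texture matrices. Builders operate on a `discretized_roi`
# (levels array with NA outside the mask). Conventions: distance-1
# neighbourhoods; 13 unique 3D offsets (26-connectivity); GLCM/GLRLM
# features computed per offset/direction then averaged; GLSZM zones and
# GLDM/NGTDM neighbourhoods use full 26-connectivity; GLDM dependence
# tolerance alpha = 0.

#' Gray-level co-occurrence matrix for one offset
#'
#' Symmetric co-occurrence counts of gray-level pairs at the given integer
#' voxel offset (each ordered pair and its reverse are both counted).
#'
#' @param d A [discretize()]d ROI.
#' @param offset Integer offset vector, e.g. `c(1, 0, 0)`.
#' @return `n_levels x n_levels` count matrix.
#' @export
glcm_matrix <- function(d, offset) {
  lv <- d$levels
  L <- d$n_levels
  sh <- shift_array(lv + 0.0, offset)
  ok <- !is.na(lv) & !is.na(sh)
  cnt <- matrix(0, L, L)
  if (any(ok)) {
    a <- lv[ok]; b <- as.integer(sh[ok])
    tb <- tabulate((a - 1L) * L + b, nbins = L * L)
    cnt <- matrix(tb, L, L, byrow = TRUE)
    cnt <- cnt + t(cnt)
  }
  cnt
}

glcm_features_one <- function(P) {
  Ns <- sum(P)
  if (Ns == 0) return(NULL)
  p <- P / Ns
  L <- nrow(p)
  iv <- seq_len(L)
  im <- matrix(iv, L, L)
  jm <- t(im)
  px <- rowSums(p)            # = colSums(p) by symmetry
  Ng <- sum(px > 0)
  mux <- sum(px * iv)
  sigx2 <- sum(px * (iv - mux)^2)
  dif <- abs(im - jm)
  # difference distribution p_{x-y}(k), k = 0..L-1
  pd <- vapply(0:(L - 1), function(k) sum(p[dif == k]), 1)
  da <- sum((0:(L - 1)) * pd)
  # sum distribution p_{x+y}(k), k = 2..2L
  sm <- im + jm
  ps <- vapply(2:(2 * L), function(k) sum(p[sm == k]), 1)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  hxy <- ent(p)
  hx <- ent(px)
  ppxy <- outer(px, px)
  nz <- p > 0 & ppxy > 0
  hxy1 <- -sum(p[nz] * log2(ppxy[nz]))
  nz2 <- ppxy > 0
  hxy2 <- -sum(ppxy[nz2] * log2(ppxy[nz2]))
  corr <- if (sigx2 > 0) (sum(p * im * jm) - mux^2) / sigx2 else 1
  offdiag <- dif > 0

  c(Autocorrelation = sum(p * im * jm),
    ClusterProminence = sum(p * (im + jm - 2 * mux)^4),
    ClusterShade = sum(p * (im + jm - 2 * mux)^3),
    ClusterTendency = sum(p * (im + jm - 2 * mux)^2),
    Contrast = sum(p * (im - jm)^2),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = ent(pd),
    DifferenceVariance = sum(pd * ((0:(L - 1)) - da)^2),
    Id = sum(p / (1 + dif)),
    Idm = sum(p / (1 + dif^2)),
    Idmn = sum(p / (1 + dif^2 / Ng^2)),
    Idn = sum(p / (1 + dif / Ng)),
    Imc1 = if (hx > 0) (hxy - hxy1) / hx else 0,
    Imc2 = sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy)))),
    InverseVariance = sum(p[offdiag] / dif[offdiag]^2),
    JointAverage = mux,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MaximumProbability = max(p),
    SumEntropy = ent(ps),
    SumSquares = sum(p * (im - mux)^2))
}

#' The 22 GLCM features
#'
#' Computes the co-occurrence features per offset and averages them over the
#' 13 unique distance-1 offsets (offsets with no voxel pairs are skipped).
#'
#' @inheritParams glcm_matrix
#' @return Named numeric vector of 22 features.
#' @export
glcm_features <- function(d) {
  offs <- unique_offsets_3d()
  acc <- NULL; k <- 0
  for (r in seq_len(nrow(offs))) {
    f <- glcm_features_one(glcm_matrix(d, offs[r, ]))
    if (is.null(f)) next
    acc <- if (is.null(acc)) f else acc + f
    k <- k + 1
  }
  if (k == 0) stop("no co-occurring voxel pairs in ROI")
  acc / k
}

#' Gray-level run-length matrix for one direction
#'
#' Counts maximal runs of equal gray level along lines in the given
#' direction; runs are broken by the mask.
#'
#' @inheritParams glcm_matrix
#' @param direction Integer direction vector (one of the 13 unique offsets).
#' @return `n_levels x max_run_length` count matrix.
#' @export
glrlm_matrix <- function(d, direction) {
  lv <- d$levels
  dm <- dim(lv)
  co <- as.matrix(expand.grid(i = seq_len(dm[1]), j = seq_len(dm[2]),
                              k = seq_len(dm[3])))
  tt <- co %*% direction
  k1 <- co[, 1] * direction[2] - co[, 2] * direction[1]
  k2 <- co[, 1] * direction[3] - co[, 3] * direction[1]
  k3 <- co[, 2] * direction[3] - co[, 3] * direction[2]
  ord <- order(k1, k2, k3, tt)
  v <- as.vector(lv)[ord]
  n <- length(v)
  newline <- c(TRUE, k1[ord][-1] != k1[ord][-n] | k2[ord][-1] != k2[ord][-n] |
                 k3[ord][-1] != k3[ord][-n])
  prev <- c(NA, v[-n])
  eq <- v == prev
  eq[is.na(eq)] <- FALSE
  run_id <- cumsum(newline | !eq)
  keep <- !is.na(v)
  idr <- run_id[keep]
  vv <- v[keep]
  rl <- rle(idr)
  run_len <- rl$lengths
  run_level <- vv[!duplicated(idr)]
  L <- d$n_levels
  Jmax <- max(run_len)
  matrix(tabulate((run_level - 1L) * Jmax + run_len, nbins = L * Jmax),
         L, Jmax, byrow = TRUE)
}

# Shared feature set for level-by-size count matrices (GLRLM run lengths,
# GLSZM zone sizes). `np` is the number of ROI voxels (for the percentage
# feature). Returns the 16 features with family-appropriate names applied
# by the caller.
size_matrix_features <- function(P, np) {
  Nr <- sum(P)
  p <- P / Nr
  iv <- seq_len(nrow(P))
  jv <- seq_len(ncol(P))
  im <- matrix(iv, nrow(P), ncol(P))
  jm <- matrix(jv, nrow(P), ncol(P), byrow = TRUE)
  mu_i <- sum(p * im)
  mu_j <- sum(p * jm)
  pp <- p[p > 0]
  c(small = sum(P / jm^2) / Nr,
    large = sum(P * jm^2) / Nr,
    gln = sum(rowSums(P)^2) / Nr,
    glnn = sum(rowSums(P)^2) / Nr^2,
    sn = sum(colSums(P)^2) / Nr,
    snn = sum(colSums(P)^2) / Nr^2,
    pct = Nr / np,
    glv = sum(p * (im - mu_i)^2),
    sv = sum(p * (jm - mu_j)^2),
    ent = -sum(pp * log2(pp)),
    lgl = sum(P / im^2) / Nr,
    hgl = sum(P * im^2) / Nr,
    small_lgl = sum(P / (im^2 * jm^2)) / Nr,
    small_hgl = sum(P * im^2 / jm^2) / Nr,
    large_lgl = sum(P * jm^2 / im^2) / Nr,
    large_hgl = sum(P * im^2 * jm^2) / Nr)
}

glrlm_names <- c("ShortRunEmphasis", "LongRunEmphasis",
                 "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                 "RunLengthNonUniformity", "RunLengthNonUniformityNormalized",
                 "RunPercentage", "GrayLevelVariance", "RunVariance",
                 "RunEntropy", "LowGrayLevelRunEmphasis",
                 "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
                 "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
                 "LongRunHighGrayLevelEmphasis")

#' The 16 GLRLM features
#'
#' Run-length features computed per direction and averaged over the 13
#' unique directions.
#'
#' @inheritParams glcm_matrix
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(d) {
  np <- sum(!is.na(d$levels))
  offs <- unique_offsets_3d()
  acc <- 0
  for (r in seq_len(nrow(offs)))
    acc <- acc + size_matrix_features(glrlm_matrix(d, offs[r, ]), np)
  out <- acc / nrow(offs)
  stats::setNames(out, glrlm_names)
}

#' Gray-level size-zone matrix
#'
#' Zones are 26-connected components of equal gray level.
#'
#' @inheritParams glcm_matrix
#' @return `n_levels x max_zone_size` count matrix.
#' @export
glszm_matrix <- function(d) {
  lv <- d$levels
  dm <- dim(lv)
  vox <- which(!is.na(lv))
  nv <- length(vox)
  lookup <- integer(prod(dm))
  lookup[vox] <- seq_len(nv)
  lin <- array(seq_len(prod(dm)) + 0.0, dm)
  offs <- unique_offsets_3d()
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    sh_lv <- shift_array(lv + 0.0, off)
    sh_lin <- shift_array(lin, off)
    ok <- !is.na(lv) & !is.na(sh_lv) & lv == sh_lv
    if (!any(ok)) next
    from <- c(from, lookup[which(ok)])
    to <- c(to, lookup[sh_lin[ok]])
  }
  g <- igraph::make_empty_graph(nv, directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  comp <- igraph::components(g)
  zone_size <- comp$csize
  zone_level <- lv[vox][match(seq_len(comp$no), comp$membership)]
  L <- d$n_levels
  Smax <- max(zone_size)
  matrix(tabulate((zone_level - 1L) * Smax + zone_size, nbins = L * Smax),
         L, Smax, byrow = TRUE)
}

glszm_names <- c("SmallAreaEmphasis", "LargeAreaEmphasis",
                 "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                 "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
                 "ZonePercentage", "GrayLevelVariance", "ZoneVariance",
                 "ZoneEntropy", "LowGrayLevelZoneEmphasis",
                 "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
                 "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
                 "LargeAreaHighGrayLevelEmphasis")

#' The 16 GLSZM features
#' @inheritParams glcm_matrix
#' @return Named numeric vector of 16 features.
#' @export
glszm_features <- function(d) {
  np <- sum(!is.na(d$levels))
  stats::setNames(size_matrix_features(glszm_matrix(d), np), glszm_names)
}

# Mean gray level of the valid 26-neighbours of every masked voxel, plus the
# per-level absolute-difference sums and counts of the NGTDM.
ngtdm_table <- function(d) {
  lv <- d$levels
  num <- array(0, dim(lv)); den <- array(0, dim(lv))
  offs <- all_offsets_3d()
  for (r in seq_len(nrow(offs))) {
    sh <- shift_array(lv + 0.0, offs[r, ])
    has <- !is.na(sh)
    sh[!has] <- 0
    num <- num + sh
    den <- den + has
  }
  sel <- !is.na(lv) & den > 0
  abar <- num[sel] / den[sel]
  lev <- lv[sel]
  L <- d$n_levels
  s <- vapply(seq_len(L), function(i) sum(abs(i - abar)[lev == i]), 1)
  n <- tabulate(lev, L)
  list(s = s, n = n, nvp = sum(sel))
}

#' The 5 NGTDM features
#'
#' Neighbourhood gray-tone difference features (Coarseness, Contrast,
#' Busyness, Complexity, Strength) with a 26-voxel neighbourhood. A flat
#' ROI has Coarseness 1e6 (capped), Contrast/Busyness/Strength 0.
#'
#' @inheritParams glcm_matrix
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(d) {
  tb <- ngtdm_table(d)
  p <- tb$n / tb$nvp
  s <- tb$s
  iv <- seq_along(p)
  act <- p > 0
  ngp <- sum(act)
  ia <- iv[act]; pa <- p[act]; sa <- s[act]
  denom_coarse <- sum(pa * sa)
  coarseness <- if (denom_coarse > 0) 1 / denom_coarse else 1e6
  contrast <- if (ngp > 1)
    sum(outer(pa, pa) * outer(ia, ia, function(a, b) (a - b)^2)) /
      (ngp * (ngp - 1)) * sum(sa) / tb$nvp else 0
  busy_den <- sum(abs(outer(ia * pa, ia * pa, `-`)))
  busyness <- if (busy_den > 0) sum(pa * sa) / busy_den else 0
  cmplx <- sum(abs(outer(ia, ia, `-`)) *
                 (outer(pa * sa, pa * sa, `+`)) /
                 (outer(pa, pa, `+`))) / tb$nvp
  strength <- if (sum(sa) > 0)
    sum(outer(pa, pa, `+`) * outer(ia, ia, function(a, b) (a - b)^2)) /
      sum(sa) else 0
  c(Coarseness = min(coarseness, 1e6), Contrast = contrast,
    Busyness = busyness, Complexity = cmplx, Strength = strength)
}

#' Gray-level dependence matrix
#'
#' Dependence of a voxel = 1 + number of 26-neighbours whose gray level
#' differs by at most `alpha` (default 0).
#'
#' @inheritParams glcm_matrix
#' @param alpha Dependence tolerance.
#' @return `n_levels x max_dependence` count matrix.
#' @export
gldm_matrix <- function(d, alpha = 0) {
  lv <- d$levels
  cnt <- array(0, dim(lv))
  offs <- all_offsets_3d()
  for (r in seq_len(nrow(offs))) {
    sh <- shift_array(lv + 0.0, offs[r, ])
    dep <- !is.na(lv) & !is.na(sh) & abs(lv - sh) <= alpha
    cnt <- cnt + dep
  }
  sel <- !is.na(lv)
  j <- cnt[sel] + 1L
  lev <- lv[sel]
  L <- d$n_levels
  Jmax <- max(j)
  matrix(tabulate((lev - 1L) * Jmax + j, nbins = L * Jmax),
         L, Jmax, byrow = TRUE)
}

gldm_names <- c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
                "GrayLevelNonUniformity", "DependenceNonUniformity",
                "DependenceNonUniformityNormalized", "GrayLevelVariance",
                "DependenceVariance", "DependenceEntropy",
                "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
                "SmallDependenceLowGrayLevelEmphasis",
                "SmallDependenceHighGrayLevelEmphasis",
                "LargeDependenceLowGrayLevelEmphasis",
                "LargeDependenceHighGrayLevelEmphasis")

#' The 14 GLDM features
#' @inheritParams gldm_matrix
#' @return Named numeric vector of 14 features.
#' @export
gldm_features <- function(d, alpha = 0) {
  f <- size_matrix_features(gldm_matrix(d, alpha), sum(!is.na(d$levels)))
  stats::setNames(f[c("small", "large", "gln", "sn", "snn", "glv", "sv",
                      "ent", "lgl", "hgl", "small_lgl", "small_hgl",
                      "large_lgl", "large_hgl")], gldm_names)
}
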