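# Internal array and numeric helpers shared across modules.

# Shift a 3D array by integer offset d: out[i] = a[i + d], NA outside.
shift_array <- function(a, d) {
  dm <- dim(a)
  out <- array(NA_real_, dm)
  dst <- lapply(1:3, function(k) seq_len(dm[k])[seq_len(dm[k]) + d[k] >= 1 &
                                                seq_len(dm[k]) + d[k] <= dm[k]])
  if (any(vapply(dst, length, 1L) == 0L)) return(out)
  src <- lapply(1:3, function(k) dst[[k]] + d[k])
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# The 13 unique 3D direction offsets (one representative per +/- pair),
# i.e. half of the 26-neighbourhood.
unique_offsets_3d <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  keep <- apply(g, 1, function(d) {
    nz <- d[d != 0]
    nz[1] > 0
  })
  unname(as.matrix(g[keep, , drop = FALSE]))
}

# All 26 neighbour offsets.
all_offsets_3d <- function() {
  u <- unique_offsets_3d()
  rbind(u, -u)
}

# Separable Gaussian smoothing of a 3D array (sigma in voxels per axis),
# with edge renormalisation so a constant field stays constant.
gauss_smooth3d <- function(a, sigma) {
  sigma <- rep_len(sigma, 3L)
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    h <- max(1L, ceiling(3 * sigma[ax]))
    w <- exp(-((-h:h)^2) / (2 * sigma[ax]^2))
    num <- array(0, dim(a))
    den <- array(0, dim(a))
    ones <- array(1, dim(a))
    for (j in seq_along(w)) {
      d <- c(0L, 0L, 0L)
      d[ax] <- (-h:h)[j]
      s <- shift_array(a, d)
      m <- shift_array(ones, d)
      s[is.na(s)] <- 0
      m[is.na(m)] <- 0
      num <- num + w[j] * s
      den <- den + w[j] * m
    }
    a <- num / den
  }
  a
}

# Cumulative trapezoidal integral of y over x, same length as x, starts at 0.
cumtrapz1 <- function(x, y) {
  n <- length(x)
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}

# Quantile convention used everywhere in the package: linear interpolation
# between order statistics (R type 7).
q_lin <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-patient substream seed derived from the cohort seed by
# counter, so adding patients never perturbs earlier ones. Kept below 2^31.
substream_seed <- function(seed, counter) {
  (abs(seed) %% 1000003L) * 2099L + counter * 7L + 11L
}
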