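# Independent brute-force enumerators for the texture matrices. These walk
# voxels/pairs/zones/runs with naive loops and are deliberately written
# without sharing any code with the package implementation.

bf_in_box <- function(p, dm) all(p >= 1) && all(p <= dm)

bf_glcm <- function(lv, offset, L) {
  dm <- dim(lv)
  cnt <- matrix(0, L, L)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    a <- lv[i, j, k]
    if (is.na(a)) next
    q <- c(i, j, k) + offset
    if (!bf_in_box(q, dm)) next
    b <- lv[q[1], q[2], q[3]]
    if (is.na(b)) next
    cnt[a, b] <- cnt[a, b] + 1
    cnt[b, a] <- cnt[b, a] + 1
  }
  cnt
}

bf_glrlm <- function(lv, dir, L) {
  dm <- dim(lv)
  at <- function(p) if (bf_in_box(p, dm)) lv[p[1], p[2], p[3]] else NA
  runs <- list()
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    p <- c(i, j, k)
    v <- lv[i, j, k]
    if (is.na(v)) next
    prev <- at(p - dir)
    if (!is.na(prev) && prev == v) next  # not a run start
    len <- 1
    q <- p + dir
    while (!is.na(at(q)) && at(q) == v) {
      len <- len + 1
      q <- q + dir
    }
    runs[[length(runs) + 1]] <- c(v, len)
  }
  rr <- do.call(rbind, runs)
  cnt <- matrix(0, L, max(rr[, 2]))
  for (r in seq_len(nrow(rr))) cnt[rr[r, 1], rr[r, 2]] <- cnt[rr[r, 1], rr[r, 2]] + 1
  cnt
}

bf_neighbors26 <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

bf_glszm <- function(lv, L) {
  dm <- dim(lv)
  nbs <- bf_neighbors26()
  seen <- array(FALSE, dm)
  zones <- list()
  idx <- which(!is.na(lv), arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p0 <- idx[r, ]
    if (seen[p0[1], p0[2], p0[3]]) next
    v <- lv[p0[1], p0[2], p0[3]]
    queue <- list(p0)
    seen[p0[1], p0[2], p0[3]] <- TRUE
    size <- 0
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (n in seq_len(nrow(nbs))) {
        q <- p + nbs[n, ]
        if (!bf_in_box(q, dm)) next
        if (seen[q[1], q[2], q[3]]) next
        w <- lv[q[1], q[2], q[3]]
        if (is.na(w) || w != v) next
        seen[q[1], q[2], q[3]] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
    zones[[length(zones) + 1]] <- c(v, size)
  }
  zz <- do.call(rbind, zones)
  cnt <- matrix(0, L, max(zz[, 2]))
  for (r in seq_len(nrow(zz))) cnt[zz[r, 1], zz[r, 2]] <- cnt[zz[r, 1], zz[r, 2]] + 1
  cnt
}

bf_ngtdm <- function(lv, L) {
  dm <- dim(lv)
  nbs <- bf_neighbors26()
  s <- numeric(L); n <- integer(L); nvp <- 0
  idx <- which(!is.na(lv), arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    vals <- c()
    for (m in seq_len(nrow(nbs))) {
      q <- p + nbs[m, ]
      if (!bf_in_box(q, dm)) next
      w <- lv[q[1], q[2], q[3]]
      if (!is.na(w)) vals <- c(vals, w)
    }
    if (length(vals) == 0) next
    v <- lv[p[1], p[2], p[3]]
    s[v] <- s[v] + abs(v - mean(vals))
    n[v] <- n[v] + 1L
    nvp <- nvp + 1
  }
  list(s = s, n = n, nvp = nvp)
}

bf_gldm <- function(lv, L, alpha = 0) {
  dm <- dim(lv)
  nbs <- bf_neighbors26()
  deps <- list()
  idx <- which(!is.na(lv), arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    v <- lv[p[1], p[2], p[3]]
    dep <- 0
    for (m in seq_len(nrow(nbs))) {
      q <- p + nbs[m, ]
      if (!bf_in_box(q, dm)) next
      w <- lv[q[1], q[2], q[3]]
      if (!is.na(w) && abs(w - v) <= alpha) dep <- dep + 1
    }
    deps[[length(deps) + 1]] <- c(v, dep + 1)
  }
  dd <- do.call(rbind, deps)
  cnt <- matrix(0, L, max(dd[, 2]))
  for (r in seq_len(nrow(dd))) cnt[dd[r, 1], dd[r, 2]] <- cnt[dd[r, 1], dd[r, 2]] + 1
  cnt
}

# Brute-force AUC: pairwise concordance of events vs non-events.
bf_auc <- function(prob, y) {
  pos <- prob[y == 1]; neg <- prob[y == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Random small discretised ROI used across the matrix-oracle tests.
random_small_roi <- function(seed, max_dim = c(4, 4, 2), max_level = 4) {
  set.seed(seed)
  dm <- c(sample(2:max_dim[1], 1), sample(2:max_dim[2], 1),
          sample(seq_len(max_dim[3]), 1))
  vol <- array(sample(seq_len(max_level), prod(dm), replace = TRUE) + 0, dm)
  mask <- array(stats::runif(prod(dm)) > 0.2, dm)
  if (sum(mask) < 2) mask[seq_len(2)] <- TRUE
  discretize(vol, mask, binning = "fixed-width", bin_width = 1)
}
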