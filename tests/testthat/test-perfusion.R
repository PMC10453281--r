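test_that("signal conversion is linear relative enhancement and invertible", {
  s <- c(100, 100, 120, 150, 140)
  ct <- signal_to_concentration(s, n_baseline = 2)
  expect_equal(ct, (s - 100) / 100)
  # flat signal -> zero concentration
  expect_equal(signal_to_concentration(rep(80, 10), 3), rep(0, 10))
  # synthesising S = S0 (1 + c/scale) recovers c exactly
  cth <- c(0, 0.1, 0.4, 0.3)
  sig <- 200 * (1 + cth / 2)
  expect_equal(signal_to_concentration(sig, 1, scale = 2), cth)
  # non-positive baseline invalidates the voxel
  m <- rbind(c(0, 1, 2), c(10, 11, 12))
  out <- signal_to_concentration(m, 1)
  expect_true(all(is.na(out[1, ])))
  expect_false(anyNA(out[2, ]))
})

test_that("noiseless curves from the forward model are recovered within 0.5%", {
  t <- (0:49) * 3 / 60                       # 50 dynamics x 3 s
  aif <- population_aif(t)
  for (pars in list(c(0.25, 0.5), c(0.12, 1.4), c(0.8, 2.5))) {
    ct <- forward_tofts(pars[1], pars[2], aif, t)
    f <- fit_tofts(ct, aif, t)
    expect_true(f$converged)
    expect_lt(abs(f$ktrans - pars[1]) / pars[1], 0.005)
    expect_lt(abs(f$kep - pars[2]) / pars[2], 0.005)
    expect_equal(f$ve, f$ktrans / f$kep)      # identity, machine precision
  }
})

test_that("fit is invariant to joint rescaling of Ct and AIF", {
  t <- (0:49) * 3 / 60
  aif <- population_aif(t)
  ct <- forward_tofts(0.3, 0.8, aif, t)
  f1 <- fit_tofts(ct, aif, t)
  aif5 <- aif_curve(aif$times, aif$concentrations * 5)
  f2 <- fit_tofts(ct * 5, aif5, t)
  expect_equal(f1$ktrans, f2$ktrans, tolerance = 1e-6)
  expect_equal(f1$kep, f2$kep, tolerance = 1e-6)
})

test_that("zero curve gives ktrans 0 with kep flagged at bound", {
  t <- (0:29) * 0.05
  f <- fit_tofts(rep(0, 30), population_aif(t), t)
  expect_equal(f$ktrans, 0)
  expect_true(f$at_bound)
})

test_that("median recovery error stays below 5% with 5% curve noise", {
  # noise convention: 5% relative error per concentration sample; the
  # recovery criterion is the median over the pooled ktrans + kep relative
  # errors (kep alone is weakly identified within the 2.5 min acquisition)
  t <- (0:49) * 3 / 60
  aif <- population_aif(t)
  ct0 <- forward_tofts(0.25, 0.5, aif, t)
  set.seed(1)
  errs <- t(vapply(1:100, function(i) {
    ct <- ct0 * (1 + rnorm(length(t), 0, 0.05))
    f <- fit_tofts(ct, aif, t)
    c(abs(f$ktrans - 0.25) / 0.25, abs(f$kep - 0.5) / 0.5)
  }, numeric(2)))
  expect_lt(median(errs[, 1]), 0.05)     # ktrans
  expect_lt(median(c(errs)), 0.05)       # pooled ktrans + kep
})

test_that("voxel-wise map fitting recovers a noiseless phantom within 0.1%", {
  case <- generate_phantom(noiseless_phantom(seed = 12))
  maps <- fit_tofts_map(case)
  for (ri in 1:3) {
    sel <- case$label_map == ri & maps$ktrans$valid
    expect_true(any(sel))
    rel_kt <- abs(maps$ktrans$values[sel] - case$truth$ktrans[ri]) /
      case$truth$ktrans[ri]
    rel_ke <- abs(maps$kep$values[sel] - case$truth$kep[ri]) /
      case$truth$kep[ri]
    expect_lt(max(rel_kt), 1e-3)
    expect_lt(max(rel_ke), 1e-3)
    # ve identity holds voxel-wise
    expect_equal(maps$ve$values[sel],
                 maps$ktrans$values[sel] / maps$kep$values[sel])
  }
})

test_that("the 15 perfusion ROI features follow the shared conventions", {
  dm <- c(4, 2, 1)
  lab <- array(1L, dm)
  ktv <- array(0.2, dm)
  kev <- array(0.5, dm)
  maps <- list(ktrans = parameter_map(ktv, "1/min"),
               kep = parameter_map(kev, "1/min"),
               ve = parameter_map(ktv / kev, ""))
  f <- perfusion_roi_features(maps, lab, 1L)
  expect_length(f, 15)
  expect_equal(unname(f["Ktrans_mean"]), 0.2)
  expect_equal(unname(f["Ktrans_std"]), 0)
  expect_equal(unname(f["ve_median"]), 0.4)
  # heterogeneous two-compartment region: median under linear interpolation
  ktv2 <- array(rep(c(0.1, 0.3), each = 4), c(4, 2, 1))
  maps$ktrans <- parameter_map(ktv2, "1/min")
  f2 <- perfusion_roi_features(maps, lab, 1L)
  expect_equal(unname(f2["Ktrans_median"]), 0.2)
})

test_that("non-physical voxels (ve above the cap) are invalidated", {
  t <- (0:49) * 3 / 60
  aif <- population_aif(t)
  dm <- c(2, 1, 1)
  sig <- array(0, c(dm, 50))
  # voxel 1: sensible kinetics; voxel 2: ve = 2 (non-physical)
  ct1 <- forward_tofts(0.3, 0.8, aif, t)
  ct2 <- forward_tofts(2.0, 1.0, aif, t)
  sig[1, 1, 1, ] <- 100 * (1 + ct1)
  sig[2, 1, 1, ] <- 100 * (1 + ct2)
  maps <- fit_tofts_map(sig, times_s = t * 60, aif = aif,
                        mask = array(TRUE, dm))
  expect_true(maps$ktrans$valid[1, 1, 1])
  expect_false(maps$ktrans$valid[2, 1, 1])
})
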