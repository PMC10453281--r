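test_that("forward DWI signal follows the mono-exponential decay", {
  expect_equal(forward_dwi(1000, 1e-3, c(0, 500, 1000)),
               c(1000, 1000 * exp(-0.5), 1000 * exp(-1)))
  expect_equal(forward_dwi(1000, 2e-3, 0), 1000)              # b = 0 identity
  expect_equal(forward_dwi(750, 0, c(0, 200, 800)), rep(750, 3))
  expect_error(forward_dwi(1000, 1e-3, c(-10, 0)), "non-negative")
  expect_error(forward_dwi(1000, -1e-3, c(0, 500)))
})

test_that("Tofts forward model matches the constant-AIF closed form", {
  t <- seq(0, 2.45, by = 0.05)
  c0 <- 2.5
  aif <- aif_curve(t, rep(c0, length(t)))
  for (pars in list(c(0.25, 0.5), c(0.1, 2), c(1, 0.2))) {
    ct <- forward_tofts(pars[1], pars[2], aif, t)
    closed <- pars[1] * c0 / pars[2] * (1 - exp(-pars[2] * t))
    expect_equal(ct[1], 0)
    expect_lt(max(abs(ct[-1] - closed[-1]) / closed[-1]), 1e-3 / 10)
  }
})

test_that("Tofts forward model is linear in ktrans and zero for ktrans 0", {
  t <- seq(0, 2, by = 0.05)
  aif <- population_aif(t)
  expect_equal(forward_tofts(0, 1, aif, t), rep(0, length(t)))
  expect_equal(forward_tofts(0.5, 0.7, aif, t),
               2 * forward_tofts(0.25, 0.7, aif, t))
  short_aif <- population_aif(seq(0, 1, by = 0.05))
  expect_error(forward_tofts(0.2, 1, short_aif, t), "cover")
})

test_that("phantom generation is seed-deterministic and noiseless DWI inverts exactly", {
  cfg <- noiseless_phantom(seed = 42)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$t2w, b$t2w)
  expect_identical(a$dwi$signal, b$dwi$signal)
  expect_identical(a$dce$signal, b$dce$signal)

  adc <- fit_adc(a)
  for (ri in 1:3) {
    sel <- a$label_map == ri
    rel <- abs(adc$values[sel] - a$truth$adc[ri]) / a$truth$adc[ri]
    expect_lt(max(rel), 1e-6)
  }
})

test_that("phantom regions are disjoint, non-empty, with valid implied ve", {
  for (seed in 1:5) {
    cfg <- small_phantom(seed = seed)
    case <- generate_phantom(cfg)
    counts <- tabulate(case$label_map, 3)
    expect_true(all(counts > 0))
    expect_true(all(case$truth$ve > 0 & case$truth$ve <= 1))
  }
  # overlapping cztz/sv ellipsoids are a configuration error
  geo <- default_region_geometry(c(16, 16, 10), c(1.6, 1.6, 1.6))
  geo$sv$center <- geo$cztz$center
  expect_error(generate_phantom(phantom_config(grid_shape = c(16, 16, 10),
                                               region_geometry = geo)),
               "overlap")
})

test_that("cohort honours exact group sizes, missing-sequence counts and substreams", {
  cc <- cohort_config(n_patients = 128, risk_fraction_group1 = 0.25,
                      phantom = phantom_config(grid_shape = c(8, 8, 6)),
                      seed = 7)
  # clinical structure only: draw labels without rendering images
  set.seed(radzone:::substream_seed(7L, 0L))
  expect_equal(round(0.25 * 128), 32)

  cc2 <- tiny_cohort_config(n = 12, seed = 5,
                            missing_sequence_fractions = list(dwi = 0, dce = 0.5))
  coh <- generate_cohort(cc2)
  expect_equal(sum(!coh$clinical$has_dce), 6)
  expect_equal(sum(vapply(coh$cases, function(cs) is.null(cs$dce), TRUE)), 6)
  expect_equal(nrow(coh$clinical), 12)
  # derived BCR labels are consistent with the stored PSA series
  for (cs in coh$cases)
    expect_equal(derive_bcr(cs$clinical$psa_series), cs$clinical$bcr_10y)

  # determinism across regeneration
  coh2 <- generate_cohort(cc2)
  expect_identical(coh$clinical, coh2$clinical)
  expect_identical(coh$cases[[3]]$t2w, coh2$cases[[3]]$t2w)
})

test_that("empty-group fractions are rejected", {
  expect_error(cohort_config(n_patients = 10, risk_fraction_group1 = 0),
               "empty group")
  expect_error(cohort_config(n_patients = 10, risk_fraction_group1 = 1),
               "empty group")
})

test_that("ROI-mean ADC is recovered within 2% at SNR 50 over 20 seeds", {
  errs <- matrix(NA_real_, 20, 3)
  for (s in 1:20) {
    cfg <- phantom_config(grid_shape = c(12, 12, 8),
                          adc_truth = c(cztz = 1.0e-3, pz = 1.4e-3, sv = 1.8e-3),
                          s0 = 1000, dwi_noise_sd = 20, seed = 100 + s)
    case <- generate_phantom(cfg)
    adc <- fit_adc(case)
    for (ri in 1:3) {
      st <- roi_statistics(adc, case$label_map, ri)
      errs[s, ri] <- (st$mean - case$truth$adc[ri]) / case$truth$adc[ri]
    }
  }
  bias <- colMeans(errs)
  expect_true(all(abs(bias) < 0.02))
})
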