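test_that("foreground segmentation handles blank, uniform and phantom images", {
  blank <- zspectrum_stack(array(0, c(8, 8, 20)), seq(6, -10, length.out = 20))
  expect_warning(m0 <- segment_foreground(blank), "empty")
  expect_false(any(m0))
  ones <- zspectrum_stack(array(1, c(8, 8, 20)), seq(6, -10, length.out = 20))
  expect_true(all(segment_foreground(ones)))
  ph <- generate_phantom(agent_preset("glucose"), c(7.4, 7.0, 6.4), 20,
                         water_preset(7, "pbs"), sat3(),
                         small_acq(matrix = c(32, 32)), snr = 50, seed = 2)
  fg <- segment_foreground(ph$stack)
  truth <- ph$labels > 0
  jaccard <- sum(fg & truth) / sum(fg | truth)
  expect_gte(jaccard, 0.95)
  expect_error(segment_foreground(ones, 1.5), "threshold_fraction")
})

test_that("voxel fits separate clean spectra from noise by R-squared", {
  acq <- small_acq()
  z <- simulate_zspectrum(agent_preset("glucose"), 20, 6.4,
                          water_preset(7, "pbs"), sat3(), acq)
  fit <- fit_voxel(z$offsets, z$signals)
  expect_gte(fit$r2, 0.999)
  expect_lt(abs(fit$water_center), 0.01)
  expect_true(fit$valid)
  # pure i.i.d. noise around a constant: R2 below the 0.97 filter
  set.seed(42)
  r2s <- replicate(200, {
    fit_voxel(z$offsets, 0.5 + rnorm(length(z$offsets), 0, 0.02))$r2
  })
  expect_gte(mean(r2s < 0.97), 0.95)
})

test_that("degenerate voxel inputs invalidate the fit instead of crashing", {
  offs <- make_offset_list(0.5, 6)
  cfit <- fit_voxel(offs, rep(0.7, length(offs)))
  expect_identical(cfit$r2, 0)
  expect_false(cfit$valid)
  nfit <- fit_voxel(offs, c(NaN, zshape(offs)[-1]))
  expect_false(nfit$valid)
  expect_error(fit_voxel(seq(-1, 1, 0.2), rep(1, 11)), "15 offsets")
})

test_that("the smoothing -> 0 limit interpolates every sample", {
  offs <- c(make_offset_list(0.2, 6), -10)
  y <- zshape(offs)
  fit <- fit_voxel(offs, y, smoothing = 0)
  expect_lt(max(abs(fit$predict(offs) - y)), 1e-9)
})

test_that("B0 correction recentres spectra without extrapolating", {
  offs <- c(make_offset_list(0.2, 6), -10)
  # already centred (symmetric spectrum): identity resampling
  y0 <- zshape(offs, cest = 0)
  fit0 <- fit_voxel(offs, y0, smoothing = 0)
  expect_identical(fit0$water_center, 0)
  z0 <- correct_b0(fit0, offs)
  expect_lt(max(abs(z0$signals - y0)), 1e-9)
  # shifted by +0.3 ppm: recovered and recentred
  ysh <- zshape(offs, center = 0.3)
  fit <- fit_voxel(offs, ysh)
  expect_lt(abs(fit$water_center - 0.3), 0.02)
  zc <- correct_b0(fit, offs)
  corr_min <- zc$offsets[which.min(replace(zc$signals, is.na(zc$signals), 2))]
  expect_lte(abs(corr_min), 0.2 + 1e-9)  # grid resolution
  # offsets shifted outside support are NA, not extrapolated
  expect_true(any(is.na(zc$signals)))
  expect_true(all(is.na(zc$signals[zc$offsets > max(offs) - fit$water_center])))
  # shift beyond the configured maximum invalidates the voxel
  far <- fit_voxel(offs, zshape(offs, center = 1.2))
  expect_null(correct_b0(far, offs, max_shift = 1))
  bad <- fit_voxel(offs, rep(1, length(offs)))
  expect_error(correct_b0(bad, offs), "invalid")
})

test_that("asymmetry ST follows its defining formula", {
  offs <- seq(-2, 2, 0.1)
  sig <- rep(1, length(offs))
  sig[which.min(abs(offs + 1.2))] <- 0.8
  sig[which.min(abs(offs - 1.2))] <- 0.7
  # spline passes through samples, so the formula is exact at grid points
  st <- compute_st(zspectrum(offs, sig), 1.2, s0 = 1)
  expect_equal(st, 0.1, tolerance = 1e-9)
  expect_equal(compute_st(zspectrum(offs, zshape(offs) * 0 + 1 - 0.5 *
                                      exp(-offs^2)), 1.2, s0 = 1), 0)
  expect_true(is.na(compute_st(zspectrum(offs, sig), 1.2, s0 = 0)))
  expect_true(is.na(compute_st(zspectrum(offs, sig), 3.0, s0 = 1)))
  # scaling signals and S0 together leaves ST unchanged (exact)
  z1 <- zspectrum(offs, sig)
  z2 <- zspectrum(offs, sig * 3.7)
  expect_equal(compute_st(z1, 1.2, 0.9), compute_st(z2, 1.2, 0.9 * 3.7),
               tolerance = 1e-14)
})

test_that("quality filter is strict and monotone in its threshold", {
  r2 <- matrix(c(1, 1, 0.97, 0.98, 0.5, NA), 2, 3)
  expect_true(all(filter_quality(matrix(1, 3, 3))))
  expect_false(any(filter_quality(matrix(0.97, 3, 3), 0.97)))  # strict >
  m <- filter_quality(r2, 0.97)
  brute <- !is.na(r2) & r2 > 0.97
  expect_identical(m, brute)
  set.seed(7)
  rr <- matrix(runif(400), 20, 20)
  prev <- filter_quality(rr, 0.1)
  for (thr in c(0.3, 0.6, 0.9, 0.97)) {
    cur <- filter_quality(rr, thr)
    expect_true(all(prev | !cur))  # raising the threshold never adds voxels
    prev <- cur
  }
})

test_that("ST maps reproduce simulator truth and stay NaN-free on mask", {
  acq <- small_acq(matrix = c(32, 32))
  w <- water_preset(7, "pbs")
  ph <- generate_phantom(agent_preset("glucose"), c(7.4, 6.8, 6.2), 20, w,
                         sat3(), acq)
  cfg <- st_config(smoothing = 0)  # noise-free: interpolation limit
  sm <- st_map(ph$stack, 1.2, cfg)
  vt <- vial_table(sm, ph)
  expect_lt(max(abs(vt$mean_st - vt$truth_st)), 1e-3)
  expect_false(any(!is.finite(sm$values[sm$mask])))
  expect_true(all(is.na(sm$values[!sm$mask])))
  # intensity rescaling leaves ST untouched (ratio metric)
  sc <- zspectrum_stack(ph$stack$data * 2.5, ph$stack$offsets)
  sm2 <- st_map(sc, 1.2, cfg)
  expect_equal(sm2$values, sm$values, tolerance = 1e-12)
  # constant fieldmap: corrected map matches the unshifted one
  sh <- add_b0_field(ph$stack, fieldmap_spec("constant", 0.3))
  smb <- st_map(sh$stack, 1.2, cfg)
  both <- smb$mask & sm$mask
  expect_gt(sum(both), 50)
  expect_lt(max(abs(smb$values[both] - sm$values[both])), 0.01)
  # empty image: all-masked map, no error
  blank <- zspectrum_stack(array(0, dim(ph$stack$data)), ph$stack$offsets)
  smE <- st_map(blank, 1.2)
  expect_false(any(smE$mask))
})

test_that("constant-shift correction is stable across shift sizes", {
  acq <- small_acq(matrix = c(16, 16))
  ph <- generate_phantom(agent_preset("glucose"), c(6.6), 20,
                         water_preset(7, "pbs"), sat3(), acq)
  sm0 <- st_map(ph$stack, 1.2)
  ref <- mean(sm0$values[sm0$mask])
  for (shift in c(-0.4, -0.2, 0.2, 0.4)) {
    sh <- add_b0_field(ph$stack, fieldmap_spec("constant", shift))
    sm <- st_map(sh$stack, 1.2)
    expect_lt(abs(mean(sm$values[sm$mask]) - ref), 0.005)
  }
})
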