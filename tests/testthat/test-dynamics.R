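fake_st_map <- function(values, mask = NULL, offset = 1.2, t = NULL) {
  values <- as.matrix(values)
  if (is.null(mask)) mask <- !is.na(values)
  structure(list(values = values, mask = mask, analysis_offset = offset,
                 r2 = values * 0 + 1, water_center = values * 0,
                 frame_time = t), class = "st_map")
}

test_that("delta maps follow the post-minus-pre formula and are additive", {
  a <- fake_st_map(matrix(0.01, 4, 4))
  b <- fake_st_map(matrix(0.03, 4, 4), t = 6)
  d <- delta_st(a, b)
  expect_true(all(abs(d$values - 2) < 1e-12))
  expect_equal(d$frame_time, 6)
  expect_true(all(delta_st(a, a)$values == 0))
  # voxel-wise additivity across frames
  set.seed(1)
  c3 <- fake_st_map(matrix(rnorm(16, 0.02, 0.01), 4, 4))
  lhs <- delta_st(a, c3)$values
  rhs <- delta_st(a, b)$values + delta_st(b, c3)$values
  expect_equal(lhs, rhs)
  expect_error(delta_st(a, fake_st_map(matrix(0.1, 3, 3))), "geometry")
  expect_error(delta_st(a, fake_st_map(matrix(0.1, 4, 4), offset = 0.8)),
               "analysis offsets")
  # joint mask: voxels invalid in either map are NA
  m <- matrix(TRUE, 4, 4); m[1, 1] <- FALSE
  d2 <- delta_st(fake_st_map(matrix(0.01, 4, 4), mask = m), b)
  expect_true(is.na(d2$values[1, 1]))
})

test_that("enhanced fraction counts positive voxels on the joint support", {
  pos <- delta_st(fake_st_map(matrix(0.01, 5, 5)),
                  fake_st_map(matrix(0.02, 5, 5)))
  neg <- delta_st(fake_st_map(matrix(0.02, 5, 5)),
                  fake_st_map(matrix(0.01, 5, 5)))
  roi <- matrix(TRUE, 5, 5)
  expect_equal(enhanced_fraction(pos, roi), 100)
  expect_equal(enhanced_fraction(neg, roi), 0)
  expect_warning(ef <- enhanced_fraction(pos, matrix(FALSE, 5, 5)),
                 "undefined")
  expect_true(is.na(ef))
  # zero-mean symmetric noise over ~1000 voxels: 50% within binomial 3 sigma
  set.seed(8)
  nz <- fake_st_map(matrix(rnorm(1024), 32, 32))
  d <- delta_st(fake_st_map(matrix(0, 32, 32)), nz)
  expect_lt(abs(enhanced_fraction(d, matrix(TRUE, 32, 32)) - 50), 5)
  # invariant to strictly positive rescaling of the underlying ST values
  s <- matrix(rnorm(100, 0, 0.01), 10, 10)
  d1 <- delta_st(fake_st_map(s * 0), fake_st_map(s))
  d2 <- delta_st(fake_st_map(s * 0), fake_st_map(s * 40))
  expect_equal(enhanced_fraction(d1, matrix(TRUE, 10, 10)),
               enhanced_fraction(d2, matrix(TRUE, 10, 10)))
})

test_that("ROI time courses track the simulated kinetics", {
  one <- roi_time_course(list(delta_st(fake_st_map(matrix(0.01, 4, 4)),
                                       fake_st_map(matrix(0.02, 4, 4), t = 6))),
                         matrix(TRUE, 4, 4), subject = 1)
  expect_equal(nrow(one), 1)
  expect_equal(one$mean_dst, 1)
  expect_equal(one$n_voxels, 16)

  acq <- small_acq(matrix = c(24, 24))
  w <- water_preset(7, "tissue")
  for (kind in c("stable", "rising")) {
    sim <- generate_dynamic_series(
      if (kind == "stable") agent_preset("3OMG") else agent_preset("glucose"),
      uptake_preset(kind, 3, 3), w, sat2(), acq)
    maps <- process_series(sim$frames, 1.2)
    dmaps <- lapply(maps[-1], delta_st, pre = maps[[1]])
    tc <- roi_time_course(dmaps, sim$roi > 0)
    expect_equal(nrow(tc), 3)
    if (kind == "rising") {
      expect_true(all(diff(tc$mean_dst) > 0))
    } else {
      expect_lt((max(tc$mean_dst) - min(tc$mean_dst)) / mean(tc$mean_dst),
                0.05)
    }
    expect_true(all(tc$enhanced_fraction >= 0 & tc$enhanced_fraction <= 100))
  }
})

test_that("Dunnett inference matches the reference implementations", {
  skip_if_not_installed("multcomp")
  set.seed(31)
  vals <- matrix(rnorm(25, mean = rep(c(0, 0.2, 0.8, 0.1, 1.5), each = 5)),
                 5, 5)
  res <- anova_dunnett(vals)
  # one-way ANOVA cross-check against stats::aov
  df <- data.frame(y = as.vector(vals),
                   g = factor(rep(seq_len(5), each = 5)))
  av <- summary(stats::aov(y ~ g, df))[[1]]
  expect_equal(res$F, av$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p_anova, av$`Pr(>F)`[1], tolerance = 1e-10)
  # Dunnett adjusted p against multcomp::glht (quasi-MC reference)
  gl <- multcomp::glht(stats::aov(y ~ g, df),
                       linfct = multcomp::mcp(g = "Dunnett"))
  p_ref <- summary(gl)$test$pvalues
  expect_equal(unname(res$comparisons$p_adj), unname(as.vector(p_ref)),
               tolerance = 2e-3)
  expect_identical(res$comparisons$frame, 2:5)
})

test_that("Dunnett handles degenerate and strong-signal cases", {
  const <- matrix(5, 4, 4)
  res <- anova_dunnett(const)
  expect_true(res$degenerate)
  expect_true(is.na(res$F))
  expect_false(any(res$comparisons$significant))
  # a +3 sd shift in the last frame at n = 5 is detected
  set.seed(9)
  shift <- matrix(rnorm(25), 5, 5)
  shift[, 5] <- shift[, 5] + 3
  expect_true(anova_dunnett(shift)$comparisons$significant[4])
  expect_error(anova_dunnett(matrix(1, 1, 3)), "two subjects")
  expect_error(anova_dunnett(matrix(1, 3, 1)), "two time points")
})

test_that("Dunnett type-I error is near nominal under the null", {
  set.seed(77)
  rej <- replicate(400, {
    any(anova_dunnett(matrix(rnorm(25), 5, 5))$comparisons$significant)
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})
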