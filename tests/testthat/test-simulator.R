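test_that("no saturation and no solute give the expected limits", {
  acq <- small_acq()
  w <- water_preset(7, "pbs")
  # B1 = 0: no saturation anywhere
  z0 <- simulate_zspectrum(agent_preset("glucose"), 20, 6.2, w,
                           saturation_scheme(0, 5), acq)
  expect_true(all(z0$signals == 1))
  # zero concentration: pure direct water saturation is symmetric about 0
  zw <- simulate_zspectrum(agent_preset("glucose"), 0, 6.2, w, sat3(), acq)
  expect_lt(abs(st_of(zw, 1.2)), 1e-10)
  expect_lt(abs(st_of(zw, 0.8)), 1e-10)
})

test_that("simulated spectra are normalised and recover at far offsets", {
  acq <- small_acq()
  for (agent in list(agent_preset("glucose"), agent_preset("3OMG"))) {
    z <- simulate_zspectrum(agent, 20, 6.6, water_preset(7, "pbs"), sat3(),
                            acq)
    expect_true(all(z$signals >= 0 & z$signals <= 1 + 1e-12))
    expect_equal(z$signals[which.min(abs(z$offsets + 10))], 1)
    # Z -> 1 away from every resonance
    expect_gt(z$signals[which.min(abs(z$offsets - 6))], 0.9)
    expect_lt(min(z$signals), 0.2)  # deep direct saturation at water
  }
})

test_that("ST grows strictly with agent concentration", {
  acq <- small_acq()
  st <- vapply(c(0, 5, 10, 20, 50), function(cc)
    st_of(simulate_zspectrum(agent_preset("glucose"), cc, 6.2,
                             water_preset(7, "pbs"), sat3(), acq)),
    numeric(1))
  expect_true(all(diff(st) > 0))
})

test_that("matrix-exponential propagation matches adaptive time integration", {
  skip_if_not_installed("deSolve")
  agent <- agent_preset("glucose")
  water <- water_preset(7, "tissue")
  offs <- make_offset_list(1.0, 4)
  acq <- acquisition_config(7, offs)
  z <- simulate_zspectrum(agent, 20, 6.2, water, sat2(), acq)
  pl <- oracle_pools(agent, 20, 6.2, water)
  zo <- oracle_zspectrum(pl$shifts, pl$R1, pl$R2, pl$f, pl$k, 7, 2,
                         z$offsets, 5)
  expect_lt(max(abs(z$signals - zo)), 1e-6)
})

test_that("phantom generation is labelled, disjoint and deterministic", {
  acq <- small_acq(matrix = c(32, 32))
  w <- water_preset(7, "pbs")
  ph <- generate_phantom(agent_preset("glucose"), c(7.4, 7.0, 6.6, 6.2), 20,
                         w, sat3(), acq)
  expect_setequal(unique(as.vector(ph$labels)), 0:4)
  # background strictly zero, noise-free vial voxels identical
  bg <- ph$stack$data[cbind(which(ph$labels == 0, arr.ind = TRUE), 3)]
  expect_true(all(bg == 0))
  v1 <- which(ph$labels == 1, arr.ind = TRUE)
  specs <- apply(v1, 1, function(rc) ph$stack$data[rc[1], rc[2], ])
  expect_true(all(specs == specs[, 1]))
  expect_equal(nrow(ph$truth), 4)
  # fixed seed => identical stacks; different seed => different noise
  p1 <- generate_phantom(agent_preset("glucose"), c(7.0, 6.4), 20, w, sat3(),
                         acq, snr = 50, seed = 11)
  p2 <- generate_phantom(agent_preset("glucose"), c(7.0, 6.4), 20, w, sat3(),
                         acq, snr = 50, seed = 11)
  p3 <- generate_phantom(agent_preset("glucose"), c(7.0, 6.4), 20, w, sat3(),
                         acq, snr = 50, seed = 12)
  expect_identical(p1$stack$data, p2$stack$data)
  expect_false(identical(p1$stack$data, p3$stack$data))
  expect_error(generate_phantom(agent_preset("glucose"), seq(6, 7.4, 0.2),
                                20, w, sat3(), acq), "7 vials")
})

test_that("dynamic series obey their uptake kinetics", {
  acq <- small_acq(matrix = c(24, 24))
  w <- water_preset(7, "tissue")
  g <- agent_preset("glucose")
  rising <- generate_dynamic_series(g, uptake_preset("rising", 3, 4), w,
                                    sat2(), acq)
  expect_length(rising$frames, 5)
  expect_equal(rising$truth$time_min, seq(0, 24, by = 6))
  expect_true(all(diff(rising$truth$st[-1]) > 0))   # post frames rise
  expect_lt(abs(rising$truth$st[1]), 1e-12)         # baseline: no agent

  stable <- generate_dynamic_series(agent_preset("3OMG"),
                                    uptake_preset("stable", 3, 4), w, sat2(),
                                    acq)
  post <- stable$truth$st[-1]
  expect_lt((max(post) - min(post)) / mean(post), 0.05)

  two <- generate_dynamic_series(g, uptake_preset("rising", 3, 1), w, sat2(),
                                 acq)
  expect_length(two$frames, 2)
  expect_error(
    generate_dynamic_series(g, uptake_preset("rising", 3, 4), w, sat2(), acq,
                            n_frames = 3),
    "does not match")
  # two disjoint tumour ROIs inside the body
  expect_setequal(unique(as.vector(rising$roi)), 0:2)
})

test_that("uptake model validates its invariants", {
  expect_error(uptake_model("rising", c_extra = c(5, 5), c_intra = c(0, 0),
                            pH_extra = c(6.4, 7.0)), "non-increasing")
  expect_error(uptake_model("stable", c_extra = -1, c_intra = 0,
                            pH_extra = 7), ">= 0")
  expect_error(uptake_model("stable", c_extra = 1, c_intra = c(0, 0),
                            pH_extra = 7), "per post frame")
  expect_warning(uptake_preset("stable", dose = 2), "1.5 and 3")
})
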