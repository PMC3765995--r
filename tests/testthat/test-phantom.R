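test_that("deformation model enforces its geometric and temporal invariants", {
  expect_error(deformation_model(endo_radius_ed = 2.3), "epi_radius_ed")
  expect_error(deformation_model(peak_circ_shortening = 1.1), "cavity")
  expect_error(deformation_model(temporal_activation = function(t) 0.5),
               "must be 0")
  expect_error(deformation_model(temporal_activation = function(t) 0),
               "attain 1")
  expect_error(deformation_model(twist_profile = function(z) z), "twist_profile")
  m <- deformation_model()
  expect_equal(m$temporal_activation(0), 0)
  expect_equal(m$temporal_activation(model_es_time(m)), 1)
})

test_that("identity deformation gives zero displacement and zero strain", {
  m <- deformation_model(peak_circ_shortening = 0, long_shortening = 0,
                         twist_profile = function(z) 0)
  # zero-activation instant of a contracting model
  d0 <- model_eulerian_displacement(deformation_model(), x = 1.5, y = 0.6,
                                    z_lab = 4, t = 0)
  expect_equal(d0$ux, 0)
  expect_equal(d0$uy, 0)
  # model with no contraction: strains vanish at every time
  for (t in c(0, 20, 44, 80)) {
    st <- model_strain_polar(m, R = c(1.3, 1.8, 2.1), t = t)
    expect_equal(st$E_rr, rep(0, 3))
    expect_equal(st$E_cc, rep(0, 3))
    expect_equal(st$E_ll, 0)
  }
})

test_that("annulus ground truth matches the closed-form Green strain", {
  # endocardial stretch 0.8 at R = R_endo: E_cc = (0.8^2 - 1)/2 = -0.18
  m <- deformation_model(endo_radius_ed = 1.0, epi_radius_ed = 2.0,
                         peak_circ_shortening = 0.2)
  st <- model_strain_polar(m, R = 1.0, t = model_es_time(m))
  expect_equal(st$E_cc, (0.8^2 - 1) / 2, tolerance = 1e-12)
  # radial stretch from area preservation: lambda_r = R / r
  r_es <- sqrt(1 - 1 + 0.8^2)
  expect_equal(st$E_rr, ((1 / r_es)^2 - 1) / 2, tolerance = 1e-12)
})

test_that("encoded phase follows the DENSE wrap arithmetic", {
  k_e <- 0.8
  # 0.5 mm displacement stays in band: 2*pi*0.4 = 0.8*pi
  expect_equal(wrap_phase(2 * pi * k_e * 0.5), 0.8 * pi, tolerance = 1e-12)
  # 1.0 mm wraps: 1.6*pi -> -0.4*pi
  expect_equal(wrap_phase(2 * pi * k_e * 1.0), -0.4 * pi, tolerance = 1e-12)
  expect_true(all(abs(wrap_phase(seq(-20, 20, by = 0.37))) <= pi + 1e-12))
})

test_that("rendered series is wrapped, masked, and matches the truth stacks", {
  fx <- mid_slice_fixture()
  s <- fx$series
  expect_true(all(s$phase_x > -pi - 1e-9 & s$phase_x <= pi + 1e-9))
  expect_equal(dim(s$magnitude), dim(s$phase_x))
  expect_equal(dim(s$magnitude), dim(s$phase_y))
  # noiseless: wrapped rendered phase equals wrap of true phase inside mask
  f <- 7
  tm <- s$truth$mask[, , f]
  expect_equal(s$phase_x[, , f][tm],
               wrap_phase(s$truth$phase_x[, , f][tm]), tolerance = 1e-12)
  # zero-deformation, zero-noise series renders identically zero phase
  m0 <- deformation_model(peak_circ_shortening = 0, long_shortening = 0,
                          twist_profile = function(z) 0)
  s0 <- render_dense_series(m0, acquisition_spec(matrix_size = 48,
                                                 n_frames = 4, noise_sd = 0),
                            slice_descriptor("mid"), rng_seed = 1,
                            store_truth = TRUE)
  expect_equal(max(abs(s0$phase_x[s0$truth$mask])), 0)
  expect_equal(max(abs(s0$phase_y[s0$truth$mask])), 0)
})

test_that("rendering rejects slices outside the ventricle", {
  m <- deformation_model()
  sl <- slice_descriptor("mid")
  sl$position <- 1.5
  expect_error(render_dense_series(m, acquisition_spec(), sl), "position")
})

test_that("cohort generation is a pure function of its specification", {
  spec <- cohort_spec(n_mice = 2, groups = cohort_groups(1, 1),
                      acquisition = acquisition_spec(matrix_size = 48,
                                                     n_frames = 4),
                      slices = "mid", seed = 3)
  c1 <- simulate_cohort(spec, conditions = "obs1_day1")
  c2 <- simulate_cohort(spec, conditions = "obs1_day1")
  expect_identical(c1$mice, c2$mice)
  expect_identical(c1$truth, c2$truth)
})

test_that("day-2 equals day-1 exactly when inter-test degradations are off", {
  spec <- cohort_spec(n_mice = 2, groups = cohort_groups(1, 1),
                      inter_test_slice_jitter_sd = 0,
                      inter_test_noise_sd = 0,
                      acquisition = acquisition_spec(matrix_size = 48,
                                                     n_frames = 4),
                      slices = "mid", seed = 3)
  co <- simulate_cohort(spec, conditions = c("obs1_day1", "obs1_day2"))
  m1 <- co$mice[[1]]
  expect_identical(m1$obs1_day1$series, m1$obs1_day2$series)
})

test_that("the default cohort mirrors the two-group nine-animal design", {
  spec <- cohort_spec()
  expect_equal(spec$n_mice, 9)
  expect_equal(vapply(spec$groups, `[[`, numeric(1), "n"),
               c(normal = 5, depressed = 4))
  prm <- densecmr:::draw_cohort_params(spec)
  expect_equal(nrow(prm), 9)
  expect_equal(sum(prm$group == "normal"), 5)
  # depressed group contracts and twists less on average (parameter means)
  expect_lt(spec$groups$depressed$peak_circ_shortening[1],
            spec$groups$normal$peak_circ_shortening[1])
})
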