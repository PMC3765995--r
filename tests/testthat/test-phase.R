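# Itoh's 1-D unwrapper: integrate wrapped phase differences.
itoh_unwrap <- function(x) {
  x[1] + c(0, cumsum(wrap_phase(diff(x))))
}

test_that("constant phase is returned unchanged", {
  ph <- matrix(0.3, 8, 8)
  mask <- matrix(TRUE, 8, 8)
  expect_equal(unwrap_phase(ph, mask), ph)
})

test_that("a wrapped 1-D ramp is recovered against the Itoh oracle", {
  true_ramp <- seq(0, 3 * pi, length.out = 60)
  wrapped <- wrap_phase(true_ramp)
  ph <- matrix(wrapped, nrow = 1)
  mask <- matrix(TRUE, nrow = 1, ncol = 60)
  un <- unwrap_phase(ph, mask)
  oracle <- itoh_unwrap(wrapped)
  # equal up to a common 2*pi multiple of the whole component
  shift <- un[1, 1] - oracle[1]
  expect_equal(shift %% (2 * pi), 0, tolerance = 1e-9)
  expect_equal(as.vector(un) - shift, oracle, tolerance = 1e-9)
  # output minus input is an integer multiple of 2*pi everywhere
  mult <- (un - ph) / (2 * pi)
  expect_equal(mult, round(mult), tolerance = 1e-9)
})

test_that("unwrapping is idempotent and gauge-invariant", {
  true_ramp <- outer(seq(0, 2.5 * pi, length.out = 20),
                     seq(0, 1.5 * pi, length.out = 20), `+`)
  mask <- matrix(TRUE, 20, 20)
  un <- unwrap_phase(wrap_phase(true_ramp), mask)
  expect_equal(unwrap_phase(un, mask), un)
  # adding 2*pi*k to the wrapped input leaves the unwrapped gradients alone
  un2 <- unwrap_phase(wrap_phase(true_ramp + 6 * pi), mask)
  expect_equal(diff(un2), diff(un), tolerance = 1e-9)
  expect_equal(t(diff(t(un2))), t(diff(t(un))), tolerance = 1e-9)
})

test_that("empty masks and disconnected components are handled", {
  ph <- matrix(0.1, 6, 6)
  expect_error(unwrap_phase(ph, matrix(FALSE, 6, 6)), "empty mask")
  # two components are unwrapped independently
  mask <- matrix(FALSE, 6, 6)
  mask[1:2, 1:2] <- TRUE
  mask[5:6, 5:6] <- TRUE
  un <- unwrap_phase(ph, mask)
  expect_true(all(!is.na(un[mask])))
  expect_true(all(is.na(un[!mask])))
})

test_that("phase converts to displacement by the encoding relation", {
  expect_equal(phase_to_displacement(0, 0.8), 0)
  expect_equal(phase_to_displacement(pi, 0.8), 0.625)
  u1 <- phase_to_displacement(1.234, 0.8)
  expect_equal(phase_to_displacement(1.234, 1.6), u1 / 2)
  expect_error(phase_to_displacement(1, -1))
})

test_that("phantom phase is recovered through wrapping to ground truth", {
  fx <- mid_slice_fixture()
  s <- fx$series
  ctr <- fx$contours
  roi <- densecmr:::rasterize_annulus(ctr, dim(s$magnitude)[1],
                                      s$pixel_spacing)
  masks <- segment_series(s, roi = roi)
  disp <- unwrap_series(s, masks)
  nf <- dim(s$phase_x)[3]
  # true phase exceeds the wrap limit somewhere (wrapping exercised) and the
  # unwrapped phase still matches the pre-wrap truth
  max_err_phase <- 0
  max_err_u <- 0
  for (f in seq_len(nf)) {
    common <- masks[[f]] & s$truth$mask[, , f]
    max_err_phase <- max(max_err_phase,
                         abs(disp$phase_x[, , f][common] -
                               s$truth$phase_x[, , f][common]))
    max_err_u <- max(max_err_u,
                     abs(disp$u_x[, , f][common] - s$truth$u_x[, , f][common]),
                     abs(disp$u_y[, , f][common] - s$truth$u_y[, , f][common]))
  }
  expect_lt(max_err_phase, 1e-3)
  expect_lt(max_err_u, 0.01 * s$pixel_spacing)
})

test_that("displacements beyond the sanity cap are flagged, not clipped", {
  n <- 16
  ph <- array(0.1, c(n, n, 2))
  mag <- array(1, c(n, n, 2))
  s <- structure(list(magnitude = mag, phase_x = ph, phase_y = ph,
                      pixel_spacing = 0.25,
                      frame_times = c(0, 7.1), slice_id = "mid",
                      slice_position = 0.5, orientation = "short_axis",
                      k_e = 0.01, fov = 4, landmark_angle = 90,
                      lv_length_ed = 8.5),
                 class = "dense_series")
  masks <- rep(list(matrix(TRUE, n, n)), 2)
  # k_e = 0.01 turns 0.1 rad into 1.6 mm -> exceeds a 1 mm cap
  expect_warning(d <- unwrap_series(s, masks, displacement_cap = 1), "cap")
  expect_gt(max(abs(d$u_x), na.rm = TRUE), 1)  # values kept, not clipped
})
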