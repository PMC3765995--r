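test_that("identity motion gives zero strain everywhere", {
  traj <- annulus_traj(twist_es_deg = 0, lambda_endo_es = 1)
  E <- compute_strain(traj)
  expect_lt(max(abs(E$E_xx), na.rm = TRUE), 1e-10)
  expect_lt(max(abs(E$E_yy), na.rm = TRUE), 1e-10)
  expect_lt(max(abs(E$E_xy), na.rm = TRUE), 1e-10)
})

test_that("uniform biaxial stretch matches the closed form", {
  g <- grid_refs(48, 0.25, function(x, y) abs(x) < 4 & abs(y) < 4)
  traj <- synthetic_trajectories(g, function(ref, t) {
    s <- if (t == 0) c(1, 1) else c(1.1, 0.9)
    cbind(ref[, 1] * s[1], ref[, 2] * s[2])
  }, frame_times = c(0, 7.1))
  for (ord in 1:2) {
    E <- compute_strain(traj, fit_order = ord)
    ok <- E$valid
    expect_equal(unname(E$E_xx[ok, 2]), rep((1.1^2 - 1) / 2, sum(ok)),
                 tolerance = 1e-9)
    expect_equal(unname(E$E_yy[ok, 2]), rep((0.9^2 - 1) / 2, sum(ok)),
                 tolerance = 1e-9)
    expect_lt(max(abs(E$E_xy[ok, 2])), 1e-9)
  }
})

test_that("Green strain is invariant under superposed rigid motion", {
  base <- annulus_traj(lambda_endo_es = 0.85, twist_es_deg = 3)
  E0 <- compute_strain(base)
  set.seed(42)
  for (k in 1:3) {
    phi <- stats::runif(1, -pi, pi)
    tr <- stats::runif(2, -1, 1)
    rigid <- base
    for (f in seq_len(dim(base$paths)[3])) {
      p <- base$paths[, , f]
      rigid$paths[, 1, f] <- cos(phi) * p[, 1] - sin(phi) * p[, 2] + tr[1]
      rigid$paths[, 2, f] <- sin(phi) * p[, 1] + cos(phi) * p[, 2] + tr[2]
    }
    E1 <- compute_strain(rigid)
    ok <- E0$valid & E1$valid
    # invariants of E (trace, determinant) are unchanged by the rotation
    tr0 <- E0$E_xx[ok, 7] + E0$E_yy[ok, 7]
    tr1 <- E1$E_xx[ok, 7] + E1$E_yy[ok, 7]
    expect_equal(tr1, tr0, tolerance = 1e-8)
    det0 <- E0$E_xx[ok, 7] * E0$E_yy[ok, 7] - E0$E_xy[ok, 7]^2
    det1 <- E1$E_xx[ok, 7] * E1$E_yy[ok, 7] - E1$E_xy[ok, 7]^2
    expect_equal(det1, det0, tolerance = 1e-8)
  }
})

test_that("projection recovers the annulus closed form and isotropic limits", {
  lam <- 0.88
  traj <- annulus_traj(lambda_endo_es = lam)
  E <- compute_strain(traj, geometry = "polar", centroids = c(0, 0))
  proj <- project_strain(E, c(0, 0), "short_axis")
  R <- sqrt(traj$ref_points[, 1]^2 + traj$ref_points[, 2]^2)
  r_es <- sqrt(R^2 - 1.2^2 + (1.2 * lam)^2)
  ok <- E$valid
  expect_lt(max(abs(proj$E_cc[ok, 7] - (((r_es / R)^2 - 1) / 2)[ok])), 2e-3)
  expect_lt(max(abs(proj$E_rr[ok, 7] - (((R / r_es)^2 - 1) / 2)[ok])), 5e-3)
  expect_true(all(proj$E_rr[ok, 7] > 0))  # incompressibility: thickening
  # isotropic tensor projects identically in every direction
  iso <- E
  iso$E_xx[] <- 0.05; iso$E_yy[] <- 0.05; iso$E_xy[] <- 0
  pi2 <- project_strain(iso, c(0, 0), "short_axis")
  expect_equal(pi2$E_rr[ok, 3], rep(0.05, sum(ok)))
  expect_equal(pi2$E_cc[ok, 3], rep(0.05, sum(ok)))
})

test_that("aggregation uses mean of segment means, not the pooled mean", {
  # two sectors with unequal point counts and different values
  n_a <- 30; n_b <- 6
  th <- c(seq(0.1, 1.2, length.out = n_a), seq(pi, pi + 0.5, length.out = n_b))
  pts <- cbind(1.7 * cos(th), 1.7 * sin(th))
  vals <- matrix(c(rep(-0.10, n_a), rep(-0.20, n_b)), ncol = 1)
  assignment <- data.frame(
    segment = c(rep("S1", n_a), rep("S2", n_b)),
    layer = "mid", stringsAsFactors = FALSE)
  curves <- aggregate_segments(vals, assignment, frame_times = 0,
                               direction = "cc")
  lc <- layer_curves(curves)
  g <- lc$value[lc$layer == "global"]
  expect_equal(g, mean(c(-0.10, -0.20)))          # mean of segment means
  expect_false(isTRUE(all.equal(g, mean(vals))))  # pooled mean differs
  # spatially uniform field: every curve equals the field value
  vals_u <- matrix(-0.12, nrow = n_a + n_b, ncol = 1)
  cu <- aggregate_segments(vals_u, assignment, 0, "cc")
  expect_true(all(abs(cu$value + 0.12) < 1e-12))
})

test_that("peaks and rates follow the sign conventions and hand case", {
  # triangle: 0 to -12% over 60 ms, back to 0 at 120 ms
  tms <- seq(0, 120, by = 10)
  v <- -12 * (1 - abs(tms - 60) / 60) / 100
  curves <- data.frame(direction = "cc", segment = "S1", layer = "mid",
                       frame = seq_along(tms), time = tms, value = v)
  class(curves) <- c("strain_curves", "data.frame")
  pk <- extract_peaks_rates(curves, es_frame = 7)
  row <- pk[pk$layer == "mid", ]
  expect_equal(row$peak_strain_pct, -12)
  expect_equal(row$peak_systolic_rate, -0.2)
  expect_equal(row$peak_diastolic_rate, 0.2)
  # constant zero curve
  curves0 <- curves; curves0$value <- 0
  pk0 <- extract_peaks_rates(curves0, es_frame = 7)
  expect_equal(pk0$peak_strain_pct[pk0$layer == "mid"], 0)
  expect_equal(pk0$peak_systolic_rate[pk0$layer == "mid"], 0)
  # too short
  short <- curves[curves$frame <= 4, ]
  expect_error(extract_peaks_rates(short), "5 frames")
  # sign diagnostic: a "contracting" ventricle with positive global cc
  bad <- curves
  bad$value <- -bad$value + 0.001   # strictly positive "circumferential" peak
  bad$layer <- "global"
  expect_warning(extract_peaks_rates(bad, es_frame = 7), "sign")
})

test_that("end systole is the global circumferential strain extremum", {
  fx <- mid_slice_fixture()
  an <- fx$analysis
  t_es <- model_es_time(fx$model)
  expect_equal(fx$series$frame_times[an$es_frame],
               t_es, tolerance = fx$series$frame_times[2])
})

test_that("rank-deficient neighbourhoods are flagged invalid", {
  # collinear points: no 2D gradient is identifiable
  g <- list(ref = cbind(seq(0, 2, by = 0.25), 0),
            roi_index = cbind(seq_len(9), rep(1L, 9)), dx = 0.25)
  traj <- synthetic_trajectories(g, function(ref, t) ref,
                                 frame_times = c(0, 7.1))
  E <- compute_strain(traj, fit_order = 1)
  expect_true(all(!E$valid))
})
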