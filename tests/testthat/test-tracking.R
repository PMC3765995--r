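annulus_inside <- function(x, y) {
  r <- sqrt(x^2 + y^2)
  r >= 1.2 & r <= 2.2
}

test_that("zero displacement leaves contours and trajectories fixed", {
  disp <- synthetic_disp_field(function(x, y, t)
    list(ux = rep(0, length(x)), uy = rep(0, length(x)),
         inside = annulus_inside(x, y)),
    n = 64, dx = 0.25, frame_times = c(0, 7.1, 14.2))
  traj <- build_trajectories(disp)
  expect_equal(traj$paths[, , 2], traj$ref_points, tolerance = 1e-9)
  expect_equal(traj$paths[, , 3], traj$ref_points, tolerance = 1e-9)
  th <- seq(0, 2 * pi, length.out = 37)[-37]
  ctr <- contours(endo = 1.3 * cbind(cos(th), sin(th)),
                  epi = 2.1 * cbind(cos(th), sin(th)))
  prop <- propagate_contours(ctr, disp)
  expect_equal(prop$contours[[3]]$endo, ctr$endo, tolerance = 1e-9)
  expect_equal(prop$contours[[3]]$epi, ctr$epi, tolerance = 1e-9)
})

test_that("affine motion is tracked exactly up to interpolation tolerance", {
  shift <- c(0.5, 0)
  rot <- 8 * pi / 180
  disp <- synthetic_disp_field(function(x, y, t) {
    if (t == 0) return(list(ux = rep(0, length(x)), uy = rep(0, length(x)),
                            inside = annulus_inside(x, y)))
    # Eulerian displacement of rotation-then-translation
    x0 <- cos(rot) * (x - shift[1]) + sin(rot) * (y - shift[2])
    y0 <- -sin(rot) * (x - shift[1]) + cos(rot) * (y - shift[2])
    list(ux = x - x0, uy = y - y0, inside = annulus_inside(x0, y0))
  }, n = 96, dx = 0.25, frame_times = c(0, 7.1))
  traj <- build_trajectories(disp)
  ref <- traj$ref_points
  want <- cbind(cos(rot) * ref[, 1] - sin(rot) * ref[, 2] + shift[1],
                sin(rot) * ref[, 1] + cos(rot) * ref[, 2] + shift[2])
  ok <- traj$valid
  expect_gt(mean(ok), 0.95)
  expect_lt(max(abs(traj$paths[ok, , 2] - want[ok, ])), 1e-3)
  # pure translation moves every contour vertex by the same offset
  disp_t <- synthetic_disp_field(function(x, y, t) {
    ux <- rep(if (t == 0) 0 else 0.5, length(x))
    list(ux = ux, uy = rep(0, length(x)),
         inside = annulus_inside(x - ux, y))
  }, n = 96, dx = 0.25, frame_times = c(0, 7.1))
  th <- seq(0, 2 * pi, length.out = 37)[-37]
  ctr <- contours(endo = 1.4 * cbind(cos(th), sin(th)),
                  epi = 2.0 * cbind(cos(th), sin(th)))
  prop <- propagate_contours(ctr, disp_t)
  expect_equal(prop$contours[[2]]$endo, ctr$endo + rep(c(0.5, 0), each = 36),
               tolerance = 1e-6)
})

test_that("phantom contraction propagates the endocardial contour correctly", {
  fx <- mid_slice_fixture()
  an <- fx$analysis
  m <- fx$model
  # radius of the propagated endo contour at end systole vs r_endo(t_es)
  s <- fx$series
  roi <- densecmr:::rasterize_annulus(fx$contours, dim(s$magnitude)[1],
                                      s$pixel_spacing)
  masks <- segment_series(s, roi = roi)
  disp <- unwrap_series(s, masks)
  prop <- propagate_contours(fx$contours, disp)
  es <- an$es_frame
  endo_es <- prop$contours[[es]]$endo
  r_meas <- mean(sqrt(endo_es[, 1]^2 + endo_es[, 2]^2))
  a <- m$temporal_activation(s$frame_times[es])
  r_true <- m$endo_radius_ed * (1 - m$peak_circ_shortening * a)
  expect_lt(abs(r_meas - r_true), 0.5 * s$pixel_spacing)
})

test_that("tracking commutes with an in-plane rigid rotation of the dataset", {
  phi <- 25 * pi / 180
  base_u <- function(x, y) {
    s <- 0.9  # deformation x = s X; its Eulerian displacement is (1 - 1/s) x
    list(ux = (1 - 1 / s) * x, uy = (1 - 1 / s) * y)
  }
  make_disp <- function(rotate) {
    synthetic_disp_field(function(x, y, t) {
      if (rotate) {
        xr <- cos(phi) * x + sin(phi) * y
        yr <- -sin(phi) * x + cos(phi) * y
      } else {
        xr <- x; yr <- y
      }
      u <- base_u(xr, yr)
      if (rotate) {
        u <- list(ux = cos(phi) * u$ux - sin(phi) * u$uy,
                  uy = sin(phi) * u$ux + cos(phi) * u$uy)
      }
      scale <- if (t == 0) 0 else 1
      # inside test in the *deformed* frame of the contracted annulus
      x0 <- x - scale * u$ux; y0 <- y - scale * u$uy
      list(ux = scale * u$ux, uy = scale * u$uy,
           inside = annulus_inside(x0, y0))
    }, n = 96, dx = 0.25, frame_times = c(0, 7.1))
  }
  t1 <- build_trajectories(make_disp(FALSE))
  t2 <- build_trajectories(make_disp(TRUE))
  # rotate t1's endpoints and compare against t2 at the rotated references
  ok1 <- t1$valid
  p1 <- t1$paths[ok1, , 2]
  ref_rot <- cbind(cos(phi) * t1$ref_points[ok1, 1] - sin(phi) * t1$ref_points[ok1, 2],
                   sin(phi) * t1$ref_points[ok1, 1] + cos(phi) * t1$ref_points[ok1, 2])
  p1_rot <- cbind(cos(phi) * p1[, 1] - sin(phi) * p1[, 2],
                  sin(phi) * p1[, 1] + cos(phi) * p1[, 2])
  # t2 tracks from grid points; compare where a rotated reference lands on one
  # (contraction is radially symmetric, so the rotated paths must contract
  # the rotated references identically)
  expect_equal(sqrt(rowSums(p1_rot^2)), 0.9 * sqrt(rowSums(ref_rot^2)),
               tolerance = 2e-3)
  ok2 <- t2$valid
  expect_equal(sqrt(rowSums(t2$paths[ok2, , 2]^2)),
               0.9 * sqrt(rowSums(t2$ref_points[ok2, ]^2)), tolerance = 2e-3)
})

test_that("contour propagation fails loudly when vertices leave the field", {
  # mask far smaller than the contours
  disp <- synthetic_disp_field(function(x, y, t)
    list(ux = rep(0, length(x)), uy = rep(0, length(x)),
         inside = sqrt(x^2 + y^2) < 0.6),
    n = 64, dx = 0.25, frame_times = c(0, 7.1))
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  ctr <- contours(endo = 1.4 * cbind(cos(th), sin(th)),
                  epi = 2.0 * cbind(cos(th), sin(th)))
  expect_error(propagate_contours(ctr, disp), "vertices")
})

test_that("contour perturbation sensitivity is reported, not absorbed", {
  fx <- mid_slice_fixture()
  sens <- contour_sensitivity(fx$series, fx$contours, sd = 0.25, rng_seed = 4)
  expect_true(all(c("cc", "rr") %in% sens$direction))
  expect_true(all(is.finite(sens$delta)))
  # a one-pixel contour perturbation visibly moves at least one global peak
  expect_gt(max(abs(sens$delta)), 0.01)
})

test_that("contours validate enclosure", {
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  expect_error(contours(endo = 2 * cbind(cos(th), sin(th)),
                        epi = cbind(cos(th), sin(th))), "enclose")
})
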