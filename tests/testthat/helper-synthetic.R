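# Synthetic fixtures shared across tests; everything is built in code.

.fixture_cache <- new.env(parent = emptyenv())

cache_fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# Grid reference points inside a predicate, with the roi_index bookkeeping
# material_trajectories carry (pixel indices on an n x n grid).
grid_refs <- function(n, dx, inside) {
  ax <- (seq_len(n) - (n + 1) / 2) * dx
  px <- rep(ax, times = n)
  py <- rep(ax, each = n)
  keep <- inside(px, py)
  idx <- cbind(rep(seq_len(n), times = n)[keep],
               rep(seq_len(n), each = n)[keep])
  list(ref = cbind(px[keep], py[keep]), roi_index = idx, dx = dx)
}

# material_trajectories from an analytic path map path_fun(ref, t) -> n x 2.
synthetic_trajectories <- function(g, path_fun, frame_times) {
  nf <- length(frame_times)
  paths <- array(NA_real_, c(nrow(g$ref), 2, nf))
  for (f in seq_len(nf)) paths[, , f] <- path_fun(g$ref, frame_times[f])
  structure(list(ref_points = g$ref, paths = paths,
                 valid = rep(TRUE, nrow(g$ref)), frame_times = frame_times,
                 pixel_spacing = g$dx, roi_index = g$roi_index),
            class = "material_trajectories")
}

# displacement_field from an analytic Eulerian map u_fun(x, y, t) ->
# list(ux, uy, inside).
synthetic_disp_field <- function(u_fun, n, dx, frame_times) {
  ax <- (seq_len(n) - (n + 1) / 2) * dx
  px <- rep(ax, times = n)
  py <- rep(ax, each = n)
  nf <- length(frame_times)
  u_x <- array(NA_real_, c(n, n, nf))
  u_y <- u_x
  mask <- array(FALSE, c(n, n, nf))
  for (f in seq_len(nf)) {
    d <- u_fun(px, py, frame_times[f])
    u_x[, , f] <- matrix(ifelse(d$inside, d$ux, NA_real_), n, n)
    u_y[, , f] <- matrix(ifelse(d$inside, d$uy, NA_real_), n, n)
    mask[, , f] <- matrix(d$inside, n, n)
  }
  structure(list(u_x = u_x, u_y = u_y, mask = mask, pixel_spacing = dx,
                 frame_times = frame_times, k_e = 0.8),
            class = "displacement_field")
}

# Annulus trajectories following the incompressible contraction + rigid
# rotation closed form (no rendering, no tracking).
annulus_traj <- function(n = 96, dx = 0.25, r_endo = 1.2, r_epi = 2.2,
                         lambda_endo_es = 0.8, twist_es_deg = 0,
                         frame_times = seq(0, 99.4, by = 7.1),
                         t_es = 44) {
  g <- grid_refs(n, dx, function(x, y) {
    r <- sqrt(x^2 + y^2)
    r >= r_endo & r <= r_epi
  })
  path_fun <- function(ref, t) {
    a <- sin(pi * pmin(t, t_es) / (2 * t_es))^2
    re_t <- r_endo * (1 - (1 - lambda_endo_es) * a)
    R <- sqrt(ref[, 1]^2 + ref[, 2]^2)
    r <- sqrt(R^2 - r_endo^2 + re_t^2)
    th <- atan2(ref[, 2], ref[, 1]) + twist_es_deg * a * pi / 180
    cbind(r * cos(th), r * sin(th))
  }
  synthetic_trajectories(g, path_fun, frame_times)
}

# Noiseless mid-slice phantom series + full slice analysis (cached: several
# tests share it).
mid_slice_fixture <- function() {
  cache_fixture("mid_slice", function() {
    m <- deformation_model()
    acq <- acquisition_spec(noise_sd = 0)
    s <- render_dense_series(m, acq, slice_descriptor("mid"), rng_seed = 1,
                             store_truth = TRUE)
    ctr <- model_contours(m)
    an <- analyze_dense_series(s, ctr)
    list(model = m, acq = acq, series = s, contours = ctr, analysis = an)
  })
}

# Small cohort study shared by pipeline tests (96 x 96, 2 mice, 10 frames).
tiny_study_fixture <- function() {
  cache_fixture("tiny_study", function() {
    spec <- cohort_spec(
      n_mice = 2, groups = cohort_groups(1, 1),
      acquisition = acquisition_spec(matrix_size = 96, n_frames = 10),
      slices = c("basal", "mid", "apical", "4ch"), seed = 11)
    list(spec = spec, study = suppressMessages(run_study(spec)))
  })
}
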