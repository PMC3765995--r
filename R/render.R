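#' DENSE acquisition parameters
#'
#' Defaults follow a typical small-animal spiral cine DENSE protocol:
#' 32 mm field of view on a 128 x 128 matrix (0.25 mm pixels), 15 frames at a
#' 7.1 ms repetition time, and a displacement encoding frequency of
#' 0.8 cycles/mm.
#'
#' @param matrix_size Image matrix (pixels per side).
#' @param fov Field of view (mm).
#' @param n_frames Number of cine frames (>= 2; protocols use 15-20).
#' @param frame_interval Frame spacing (ms).
#' @param k_e Displacement encoding frequency (cycles/mm).
#' @param noise_sd Phase noise standard deviation (radians).
#' @param magnitude_noise_sd Magnitude image noise standard deviation
#'   (arbitrary units; tissue signal is 1).
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(matrix_size = 128, fov = 32, n_frames = 15,
                             frame_interval = 7.1, k_e = 0.8,
                             noise_sd = 0.1, magnitude_noise_sd = 0.05) {
  stopifnot(k_e > 0, n_frames >= 2, matrix_size >= 8, fov > 0,
            frame_interval > 0, noise_sd >= 0, magnitude_noise_sd >= 0)
  structure(list(matrix_size = as.integer(matrix_size), fov = fov,
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval, k_e = k_e,
                 noise_sd = noise_sd,
                 magnitude_noise_sd = magnitude_noise_sd,
                 pixel_spacing = fov / matrix_size),
            class = "acquisition_spec")
}

#' Slice descriptor
#'
#' @param id One of `"basal"`, `"mid"`, `"apical"` (short-axis) or `"4ch"`,
#'   `"2ch"` (long-axis).
#' @param position Normalized end-diastolic long-axis position of a
#'   short-axis slice (0 = apex, 1 = base); ignored for long-axis views.
#'   Defaults place the mid slice at 50% of the length with the apical and
#'   basal slices 20% below and above it.
#' @return An object of class `slice_descriptor`.
#' @export
slice_descriptor <- function(id = c("mid", "basal", "apical", "4ch", "2ch"),
                             position = NULL) {
  id <- match.arg(id)
  orientation <- if (id %in% c("4ch", "2ch")) "long_axis" else "short_axis"
  if (is.null(position)) {
    position <- switch(id, apical = 0.3, mid = 0.5, basal = 0.7, NA_real_)
  }
  structure(list(id = id, orientation = orientation, position = position),
            class = "slice_descriptor")
}

#' Render a wrapped DENSE image series from a deformation model
#'
#' Synthesizes the magnitude stack and the two displacement-encoded phase
#' stacks a cine DENSE acquisition would produce for one slice.  Inside the
#' myocardium the phase encodes the in-plane Eulerian displacement,
#' `wrap(2*pi*k_e*u + noise)`; outside it the phase is uniform random (no
#' signal coherence), as in real data.
#'
#' @param model A [deformation_model()].
#' @param acq An [acquisition_spec()].
#' @param slice A [slice_descriptor()].
#' @param rng_seed Optional integer seed for the noise streams.
#' @param store_truth If `TRUE`, attach the noise-free pre-wrap phase and true
#'   displacement stacks (for validation).
#' @return An object of class `dense_series`: arrays `magnitude`, `phase_x`,
#'   `phase_y` of dimension `[x, y, frame]`, plus acquisition metadata.
#' @export
render_dense_series <- function(model, acq = acquisition_spec(),
                                slice = slice_descriptor("mid"),
                                rng_seed = NULL, store_truth = FALSE) {
  stopifnot(inherits(model, "deformation_model"),
            inherits(acq, "acquisition_spec"),
            inherits(slice, "slice_descriptor"))
  if (slice$orientation == "short_axis" &&
      (slice$position < 0 || slice$position > 1)) {
    stop("slice position must lie within the model length (0..1 normalized)")
  }
  with_local_seed(rng_seed, {
    n <- acq$matrix_size
    dx <- acq$pixel_spacing
    ax <- pixel_axes(n, dx)
    frame_times <- (seq_len(acq$n_frames) - 1) * acq$frame_interval
    xg <- matrix(ax, n, n)
    yg <- matrix(ax, n, n, byrow = TRUE)
    mag <- array(NA_real_, c(n, n, acq$n_frames))
    phx <- mag; phy <- mag
    if (store_truth) {
      tr_phx <- mag; tr_phy <- mag; tr_ux <- mag; tr_uy <- mag
      tr_mask <- array(FALSE, dim(mag))
    }
    for (f in seq_len(acq$n_frames)) {
      t <- frame_times[f]
      if (slice$orientation == "short_axis") {
        d <- model_eulerian_displacement(model, as.vector(xg), as.vector(yg),
                                         z_lab = slice$position * model$lv_length_ed,
                                         t = t)
        u1 <- d$ux; u2 <- d$uy
      } else {
        # long-axis: image x across the ventricle, image y along it
        z <- as.vector(yg) + model$lv_length_ed / 2
        d <- model_eulerian_displacement_la(model, as.vector(xg), z, t = t)
        u1 <- d$ux; u2 <- d$uz
      }
      inside <- d$inside
      if (!any(inside)) {
        stop("slice '", slice$id, "' contains no myocardial pixels at frame ", f)
      }
      p1 <- stats::runif(n * n, -pi, pi)
      p2 <- stats::runif(n * n, -pi, pi)
      p1[inside] <- wrap_phase(2 * pi * acq$k_e * u1[inside] +
                                 stats::rnorm(sum(inside), 0, acq$noise_sd))
      p2[inside] <- wrap_phase(2 * pi * acq$k_e * u2[inside] +
                                 stats::rnorm(sum(inside), 0, acq$noise_sd))
      m <- 0.08 + stats::rnorm(n * n, 0, acq$magnitude_noise_sd)
      m[inside] <- 1 + stats::rnorm(sum(inside), 0, acq$magnitude_noise_sd)
      mag[, , f] <- m
      phx[, , f] <- p1
      phy[, , f] <- p2
      if (store_truth) {
        t1 <- rep(NA_real_, n * n); t2 <- t1
        t1[inside] <- 2 * pi * acq$k_e * u1[inside]
        t2[inside] <- 2 * pi * acq$k_e * u2[inside]
        tr_phx[, , f] <- t1; tr_phy[, , f] <- t2
        tr_ux[, , f] <- u1; tr_uy[, , f] <- u2
        tr_mask[, , f] <- inside
      }
    }
    out <- structure(list(
      magnitude = mag, phase_x = phx, phase_y = phy,
      pixel_spacing = dx, frame_times = frame_times,
      slice_id = slice$id, slice_position = slice$position,
      orientation = slice$orientation, k_e = acq$k_e,
      fov = acq$fov, landmark_angle = 90,
      lv_length_ed = model$lv_length_ed
    ), class = "dense_series")
    if (store_truth) {
      out$truth <- list(phase_x = tr_phx, phase_y = tr_phy,
                        u_x = tr_ux, u_y = tr_uy, mask = tr_mask)
    }
    out
  })
}

#' @export
print.dense_series <- function(x, ...) {
  cat(sprintf("DENSE series: %s slice (%s), %d x %d x %d frames, %.3g mm pixels, k_e = %.2f cycles/mm\n",
              x$slice_id, x$orientation, dim(x$magnitude)[1],
              dim(x$magnitude)[2], dim(x$magnitude)[3],
              x$pixel_spacing, x$k_e))
  invisible(x)
}

#' Reference (end-diastolic) myocardial contours of a model slice
#'
#' For a short-axis slice these are the endocardial and epicardial circles at
#' end diastole; these are the contours an observer would draw on frame 1.
#'
#' @param model A [deformation_model()].
#' @param slice A [slice_descriptor()] (short-axis).
#' @param n_vertices Number of polygon vertices.
#' @return A `contours` object (see [contours()]).
#' @export
model_contours <- function(model, slice = slice_descriptor("mid"),
                           n_vertices = 72) {
  stopifnot(slice$orientation == "short_axis")
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  contours(endo = cbind(model$endo_radius_ed * cos(th),
                        model$endo_radius_ed * sin(th)),
           epi = cbind(model$epi_radius_ed * cos(th),
                       model$epi_radius_ed * sin(th)),
           frame = 1L, landmark_angle = 90)
}
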