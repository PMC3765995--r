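#' Myocardial contour pair
#'
#' Closed endocardial and epicardial polylines in physical coordinates
#' (mm, origin at the image centre), as drawn at one frame.
#'
#' @param endo,epi n x 2 matrices of vertices (mm).  `epi` must strictly
#'   enclose `endo`.
#' @param frame Frame index the contours refer to (1-based).
#' @param landmark_angle Anatomical reference angle (degrees,
#'   counter-clockwise from +x) used as the origin of segment numbering.
#' @return An object of class `contours`.
#' @export
contours <- function(endo, epi, frame = 1L, landmark_angle = 90) {
  endo <- as.matrix(endo); epi <- as.matrix(epi)
  stopifnot(ncol(endo) == 2, ncol(epi) == 2, nrow(endo) >= 3, nrow(epi) >= 3)
  inside <- points_in_polygon(endo[, 1], endo[, 2], epi)
  if (!all(inside)) {
    stop("epicardial contour must strictly enclose the endocardial contour")
  }
  structure(list(endo = endo, epi = epi, frame = as.integer(frame),
                 landmark_angle = landmark_angle),
            class = "contours")
}

#' Perturb contours as a second observer would
#'
#' Applies a smooth angular perturbation to the radius of both contours
#' (low-order Fourier modes), emulating observer-dependent contouring.
#'
#' @param ctr A [contours()] object.
#' @param sd Radial perturbation standard deviation (mm).
#' @param n_modes Number of Fourier modes in the perturbation.
#' @param rng_seed Optional seed.
#' @return A perturbed `contours` object.
#' @export
perturb_contours <- function(ctr, sd, n_modes = 3, rng_seed = NULL) {
  if (sd <= 0) return(ctr)
  with_local_seed(rng_seed, {
    perturb <- function(poly) {
      cen <- polygon_centroid(poly)
      dxv <- poly[, 1] - cen[1]; dyv <- poly[, 2] - cen[2]
      th <- atan2(dyv, dxv)
      r <- sqrt(dxv^2 + dyv^2)
      dr <- rep(stats::rnorm(1, 0, sd / sqrt(2 * n_modes + 1)), length(th))
      for (k in seq_len(n_modes)) {
        dr <- dr + stats::rnorm(1, 0, sd / sqrt(2 * n_modes + 1)) * cos(k * th) +
          stats::rnorm(1, 0, sd / sqrt(2 * n_modes + 1)) * sin(k * th)
      }
      cbind(cen[1] + (r + dr) * cos(th), cen[2] + (r + dr) * sin(th))
    }
    contours(perturb(ctr$endo), perturb(ctr$epi), ctr$frame, ctr$landmark_angle)
  })
}

# Rasterize an annular region (inside epi, outside endo) onto the pixel grid.
rasterize_annulus <- function(ctr, n, pixel_spacing) {
  ax <- pixel_axes(n, pixel_spacing)
  # only pixels inside the epicardial bounding box can be in the annulus
  ii <- which(ax >= min(ctr$epi[, 1]) - pixel_spacing &
                ax <= max(ctr$epi[, 1]) + pixel_spacing)
  jj <- which(ax >= min(ctr$epi[, 2]) - pixel_spacing &
                ax <= max(ctr$epi[, 2]) + pixel_spacing)
  px <- rep(ax[ii], times = length(jj))
  py <- rep(ax[jj], each = length(ii))
  m <- points_in_polygon(px, py, ctr$epi) & !points_in_polygon(px, py, ctr$endo)
  out <- matrix(FALSE, n, n)
  out[ii, jj] <- m
  out
}

# Contour radius as a periodic function of angle about its centroid
# (for transmural depth normalization; contours are star-shaped here).
contour_radius_fun <- function(poly, centre) {
  th <- atan2(poly[, 2] - centre[2], poly[, 1] - centre[1])
  r <- sqrt((poly[, 1] - centre[1])^2 + (poly[, 2] - centre[2])^2)
  ord <- order(th)
  th <- th[ord]; r <- r[ord]
  # periodic padding
  th2 <- c(th - 2 * pi, th, th + 2 * pi)
  r2 <- c(r, r, r)
  stats::approxfun(th2, r2)
}

#' Propagate end-diastolic contours through the cardiac cycle
#'
#' Each contour vertex `v` is a material point; its position at frame `t` is
#' the location `x` solving `x - u(x, t) = v`, found by fixed-point iteration
#' on the gridded Eulerian displacement field.
#'
#' @param initial A [contours()] object drawn at frame 1 (end diastole).
#' @param disp A `displacement_field` (see [unwrap_series()]).
#' @param rasterize If `TRUE`, also return per-frame masks rasterized from
#'   the propagated contours.
#' @return A list with `contours` (list of `contours` per frame), `centroids`
#'   (frame x 2 matrix of epicardial centroids) and optionally `masks`.
#' @export
propagate_contours <- function(initial, disp, rasterize = FALSE) {
  stopifnot(inherits(initial, "contours"), inherits(disp, "displacement_field"))
  nf <- dim(disp$u_x)[3]
  n <- dim(disp$u_x)[1]
  verts <- rbind(initial$endo, initial$epi)
  n_endo <- nrow(initial$endo)
  paths <- track_points(verts, disp)
  n_bad <- sum(!paths$valid)
  if (n_bad > 0.2 * nrow(verts)) {
    stop(sprintf("contour propagation failed: %d of %d vertices left the displacement field support",
                 n_bad, nrow(verts)))
  }
  if (n_bad > 0) {
    message(n_bad, " contour vertices left the field support; ",
            "kept at nearest valid position")
  }
  out_contours <- vector("list", nf)
  centroids <- matrix(NA_real_, nf, 2)
  for (f in seq_len(nf)) {
    endo_f <- paths$positions[seq_len(n_endo), , f]
    epi_f <- paths$positions[n_endo + seq_len(nrow(initial$epi)), , f]
    out_contours[[f]] <- structure(
      list(endo = endo_f, epi = epi_f, frame = f,
           landmark_angle = initial$landmark_angle),
      class = "contours")
    centroids[f, ] <- polygon_centroid(epi_f)
  }
  res <- list(contours = out_contours, centroids = centroids)
  if (rasterize) {
    res$masks <- lapply(out_contours, rasterize_annulus, n = n,
                        pixel_spacing = disp$pixel_spacing)
  }
  res
}
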