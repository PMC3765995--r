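# Solve x - u(x, t) = X0 for every reference point and frame by fixed-point
# iteration x <- X0 + u(x, t) on the gridded Eulerian field (bilinear
# interpolation, with a nearest-mean collar extension so sampling stays
# defined just outside the mask).  Exact for affine fields; converges
# whenever the displacement gradient is subunit, which holds for physiologic
# cardiac motion at cine frame rates.
track_points <- function(ref_points, disp, max_iter = 25, tol = 1e-6) {
  n_pts <- nrow(ref_points)
  nf <- dim(disp$u_x)[3]
  np <- dim(disp$u_x)[1]
  dx <- disp$pixel_spacing
  # work on the field bounding box; everything outside is NA anyway
  mask_any <- apply(disp$mask, c(1, 2), any)
  bb <- mask_bbox(mask_any, margin = 4L)
  ri <- bb[1]:bb[2]; ci <- bb[3]:bb[4]
  c0 <- (np + 1) / 2 - (bb[1] - 1)
  c0j <- (np + 1) / 2 - (bb[3] - 1)
  positions <- array(NA_real_, c(n_pts, 2, nf))
  ok_all <- rep(TRUE, n_pts)
  cur_x <- ref_points[, 1]
  cur_y <- ref_points[, 2]
  for (f in seq_len(nf)) {
    ufx <- fill_collar(disp$u_x[ri, ci, f])
    ufy <- fill_collar(disp$u_y[ri, ci, f])
    for (it in seq_len(max_iter)) {
      xi <- cur_x / dx + c0
      yi <- cur_y / dx + c0j
      sx <- bilinear(ufx, xi, yi)
      sy <- bilinear(ufy, xi, yi)
      na <- is.na(sx) | is.na(sy)
      new_x <- ref_points[, 1] + sx
      new_y <- ref_points[, 2] + sy
      # points with no field support stay where they are
      new_x[na] <- cur_x[na]; new_y[na] <- cur_y[na]
      delta <- pmax(abs(new_x - cur_x), abs(new_y - cur_y))
      cur_x <- new_x; cur_y <- new_y
      if (max(delta) < tol) break
    }
    xi <- cur_x / dx + c0
    yi <- cur_y / dx + c0j
    ok_f <- !is.na(bilinear(ufx, xi, yi))
    positions[, 1, f] <- cur_x
    positions[, 2, f] <- cur_y
    ok_all <- ok_all & ok_f
  }
  list(positions = positions, valid = ok_all)
}

#' Build Lagrangian material-point trajectories
#'
#' Reference points are the pixel centres inside the end-diastolic region of
#' interest; for each frame, each point's current position is obtained by
#' inverting the Eulerian map `x -> x - u(x, t)` (the point now at `x`
#' started at `x - u`).
#'
#' @param disp A `displacement_field` from [unwrap_series()].
#' @param roi Logical matrix: end-diastolic myocardial region of interest
#'   (typically rasterized initial contours).  Defaults to the frame-1 mask.
#' @return An object of class `material_trajectories`: `ref_points`
#'   (n x 2, mm), `paths` (n x 2 x frames, mm), logical `valid`, and
#'   `frame_times`.
#' @export
build_trajectories <- function(disp, roi = NULL) {
  stopifnot(inherits(disp, "displacement_field"))
  nf <- dim(disp$u_x)[3]
  for (f in seq_len(nf)) {
    if (!any(disp$mask[, , f])) stop("empty myocardial mask at frame ", f)
  }
  if (is.null(roi)) roi <- disp$mask[, , 1]
  np <- dim(disp$u_x)[1]
  dx <- disp$pixel_spacing
  ax <- pixel_axes(np, dx)
  idx <- which(roi, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty end-diastolic region of interest")
  ref <- cbind(ax[idx[, 1]], ax[idx[, 2]])
  tr <- track_points(ref, disp)
  structure(list(ref_points = ref, paths = tr$positions, valid = tr$valid,
                 frame_times = disp$frame_times,
                 pixel_spacing = dx, roi_index = idx, disp = disp),
            class = "material_trajectories")
}

#' @export
print.material_trajectories <- function(x, ...) {
  cat(sprintf("Material trajectories: %d points x %d frames (%d valid)\n",
              nrow(x$ref_points), dim(x$paths)[3], sum(x$valid)))
  invisible(x)
}
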