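#' Green-Lagrange strain tensors from material trajectories
#'
#' For each material point and frame, the local deformation map is fit by
#' least squares over the reference offsets versus current offsets of all
#' neighbours within `neighborhood_radius`; the deformation gradient `F` is
#' the linear part of that local fit at the point, and the Green-Lagrange
#' tensor is `E = (F'F - I)/2`, which is invariant under superposed rigid
#' motion.
#'
#' Two local frames are available.  `geometry = "cartesian"` fits the map in
#' image coordinates, with quadratic terms by default (`fit_order = 2`):
#' near the wall edges the neighbourhood is one-sided and a purely linear fit
#' (`fit_order = 1`, the textbook estimator) aliases the transmural curvature
#' of the displacement field into `F`.  `geometry = "polar"` (used for
#' short-axis slices) fits the map between the reference and deformed polar
#' frames about the supplied centroids, with a cubic radial / quadratic
#' circumferential basis; annular wall motion is nearly linear in these
#' coordinates, so the steep transmural strain gradient across a wall only a
#' few pixels thick is recovered without the geometric bias a Cartesian
#' polynomial basis suffers there.  The returned tensor components are
#' always Cartesian (the polar-frame tensor is rotated back per point).
#'
#' @param traj A `material_trajectories` object.
#' @param neighborhood_radius Neighbour search radius (mm); default 0.75 mm
#'   (3 pixels at the default 0.25 mm resolution).
#' @param fit_order For `geometry = "cartesian"`: 1 for a linear local fit,
#'   2 (default) to include quadratic terms.
#' @param geometry Local frame for the fit; see Details.
#' @param centroids For `geometry = "polar"`: LV centroid per frame
#'   (frames x 2 matrix, mm), e.g. from [propagate_contours()]; a single
#'   centroid is recycled across frames.
#' @return An object of class `strain_tensor_field` with matrices `E_xx`,
#'   `E_xy`, `E_yy` of dimension `[points, frames]` (NA for invalid points)
#'   and the per-point validity flag.
#' @export
compute_strain <- function(traj, neighborhood_radius = 0.75, fit_order = 2,
                           geometry = c("cartesian", "polar"),
                           centroids = NULL) {
  stopifnot(inherits(traj, "material_trajectories"), fit_order %in% c(1, 2))
  geometry <- match.arg(geometry)
  if (geometry == "polar" && !is.null(traj$disp)) {
    # trajectories built from a displacement field carry it along: fit each
    # frame's exact Eulerian pixel pairs (x, X = x - u) directly, avoiding
    # any interpolation of the field
    return(strain_polar_scattered(traj, neighborhood_radius, centroids))
  }
  ref <- traj$ref_points
  n_pts <- nrow(ref)
  nf <- dim(traj$paths)[3]
  dx_px <- traj$pixel_spacing
  valid <- traj$valid
  if (geometry == "polar") {
    if (is.null(centroids)) stop("polar geometry requires centroids")
    if (is.null(dim(centroids))) {
      centroids <- matrix(centroids, nf, 2, byrow = TRUE)
    }
    stopifnot(nrow(centroids) == nf)
  }

  # neighbour pairs via the pixel-grid stencil (reference points are pixel
  # centres, so offsets within the radius come from a fixed integer stencil)
  idx <- traj$roi_index
  np_grid <- max(idx) + 2L
  id_grid <- matrix(NA_integer_, np_grid, np_grid)
  keep <- which(valid)
  id_grid[idx[keep, , drop = FALSE]] <- keep
  r_px <- neighborhood_radius / dx_px
  sten <- expand.grid(di = -floor(r_px):floor(r_px),
                      dj = -floor(r_px):floor(r_px))
  sten <- sten[sten$di^2 + sten$dj^2 <= r_px^2 &
                 !(sten$di == 0 & sten$dj == 0), ]
  pair_p <- integer(0); pair_q <- integer(0)
  for (s in seq_len(nrow(sten))) {
    i2 <- idx[, 1] + sten$di[s]
    j2 <- idx[, 2] + sten$dj[s]
    ok <- i2 >= 1 & j2 >= 1 & i2 <= np_grid & j2 <= np_grid & valid
    q <- rep(NA_integer_, n_pts)
    q[ok] <- id_grid[cbind(i2[ok], j2[ok])]
    has <- !is.na(q)
    pair_p <- c(pair_p, which(has))
    pair_q <- c(pair_q, q[has])
  }

  wrap_angle <- function(x) atan2(sin(x), cos(x))
  if (geometry == "cartesian") {
    dXx <- ref[pair_q, 1] - ref[pair_p, 1]
    dXy <- ref[pair_q, 2] - ref[pair_p, 2]
    # the relative displacement of a neighbour vanishes at zero offset, so
    # no intercept enters the fit
    B <- cbind(dXx, dXy)
    if (fit_order == 2) B <- cbind(B, dXx^2, dXx * dXy, dXy^2)
    min_nb <- if (fit_order == 2) 6L else 3L
  } else {
    R0 <- sqrt((ref[, 1] - centroids[1, 1])^2 + (ref[, 2] - centroids[1, 2])^2)
    th0 <- atan2(ref[, 2] - centroids[1, 2], ref[, 1] - centroids[1, 1])
    if (any(R0[valid] < 1e-9)) stop("material point at the centroid")
    dR <- R0[pair_q] - R0[pair_p]
    dC <- R0[pair_p] * wrap_angle(th0[pair_q] - th0[pair_p])
    B <- cbind(dR, dC, dR^2, dR * dC, dC^2, dR^3)
    min_nb <- 7L
  }
  n_basis <- ncol(B)
  n_nb <- tabulate(pair_p, n_pts)
  good <- valid & n_nb >= min_nb

  # per-point sums of all basis products (grouped by point), then the
  # inverse Gram matrix of each point's neighbour configuration
  rowsum_full <- function(v) {
    rs <- rowsum(v, pair_p)
    out <- numeric(n_pts)
    out[as.integer(rownames(rs))] <- rs
    out
  }
  gram <- array(0, c(n_pts, n_basis, n_basis))
  for (j in seq_len(n_basis)) for (k in j:n_basis) {
    s <- rowsum_full(B[, j] * B[, k])
    gram[, j, k] <- s
    gram[, k, j] <- s
  }
  ginv <- array(NA_real_, c(n_pts, n_basis, n_basis))
  for (p in which(good)) {
    gi <- tryCatch(solve(gram[p, , ]), error = function(e) NULL)
    if (is.null(gi) || !all(is.finite(gi))) {
      good[p] <- FALSE  # rank-deficient neighbour configuration
    } else {
      ginv[p, , ] <- gi
    }
  }

  E_xx <- matrix(NA_real_, n_pts, nf)
  E_xy <- E_xx; E_yy <- E_xx
  rhs_1 <- matrix(0, n_pts, n_basis)
  rhs_2 <- matrix(0, n_pts, n_basis)
  for (f in seq_len(nf)) {
    cx <- traj$paths[, 1, f]
    cy <- traj$paths[, 2, f]
    if (geometry == "cartesian") {
      d1 <- cx[pair_q] - cx[pair_p]
      d2 <- cy[pair_q] - cy[pair_p]
    } else {
      rc <- sqrt((cx - centroids[f, 1])^2 + (cy - centroids[f, 2])^2)
      thc <- atan2(cy - centroids[f, 2], cx - centroids[f, 1])
      d1 <- rc[pair_q] - rc[pair_p]
      d2 <- rc[pair_p] * wrap_angle(thc[pair_q] - thc[pair_p])
    }
    for (j in seq_len(n_basis)) {
      rhs_1[, j] <- rowsum_full(d1 * B[, j])
      rhs_2[, j] <- rowsum_full(d2 * B[, j])
    }
    # F is the linear part of the fitted local map
    F11 <- rowSums(ginv[, 1, ] * rhs_1)
    F12 <- rowSums(ginv[, 2, ] * rhs_1)
    F21 <- rowSums(ginv[, 1, ] * rhs_2)
    F22 <- rowSums(ginv[, 2, ] * rhs_2)
    exx <- 0.5 * (F11^2 + F21^2 - 1)
    eyy <- 0.5 * (F12^2 + F22^2 - 1)
    exy <- 0.5 * (F11 * F12 + F21 * F22)
    if (geometry == "polar") {
      # rotate the polar-frame tensor (rr, rc, cc) back to image axes
      erx <- (ref[, 1] - centroids[1, 1]) / R0
      ery <- (ref[, 2] - centroids[1, 2]) / R0
      ecx <- -ery; ecy <- erx
      t_xx <- erx^2 * exx + 2 * erx * ecx * exy + ecx^2 * eyy
      t_yy <- ery^2 * exx + 2 * ery * ecy * exy + ecy^2 * eyy
      t_xy <- erx * ery * exx + (erx * ecy + ery * ecx) * exy + ecx * ecy * eyy
      exx <- t_xx; eyy <- t_yy; exy <- t_xy
    }
    E_xx[, f] <- exx
    E_yy[, f] <- eyy
    E_xy[, f] <- exy
  }
  E_xx[!good, ] <- NA_real_
  E_xy[!good, ] <- NA_real_
  E_yy[!good, ] <- NA_real_
  structure(list(E_xx = E_xx, E_xy = E_xy, E_yy = E_yy,
                 valid = good, ref_points = ref,
                 frame_times = traj$frame_times,
                 neighborhood_radius = neighborhood_radius,
                 geometry = geometry),
            class = "strain_tensor_field")
}

# Polar-frame strain fit over the exact scattered Eulerian pairs of each
# frame.  Every masked pixel at frame f provides an exact correspondence
# between its current position x and its reference position X = x - u(x,f).
# Around each material point the local deformation is fit in polar
# coordinates (reference frame about the end-diastolic centroid, deformed
# frame about the frame-f centroid) in two stages:
#   1. a forward fit locates the point's deformed position;
#   2. the *inverse* map (reference coordinates regressed on the exact
#      deformed pixel positions) is fit with a cubic radial / quadratic
#      circumferential basis and inverted, F = G^-1.
# Regressing on the exact deformed positions avoids the errors-in-variables
# attenuation a forward fit suffers when pixel noise enters its predictors;
# the cubic radial term (stabilized under noise by a ridge prior at the
# physical scale of wall curvature) extrapolates correctly over the thin
# band near the endocardial edge where wall thinning leaves no pixel
# centres.  The circumferential half-window is twice the radial one: annular
# wall motion is nearly linear along the wall, so the wider window averages
# noise without bias.
strain_polar_scattered <- function(traj, neighborhood_radius, centroids) {
  disp <- traj$disp
  ref <- traj$ref_points
  n_pts <- nrow(ref)
  nf <- dim(traj$paths)[3]
  if (is.null(centroids)) stop("polar geometry requires centroids")
  if (is.null(dim(centroids))) {
    centroids <- matrix(centroids, nf, 2, byrow = TRUE)
  }
  stopifnot(nrow(centroids) == nf)
  np <- dim(disp$u_x)[1]
  ax <- pixel_axes(np, disp$pixel_spacing)
  R0 <- sqrt((ref[, 1] - centroids[1, 1])^2 + (ref[, 2] - centroids[1, 2])^2)
  th0 <- atan2(ref[, 2] - centroids[1, 2], ref[, 1] - centroids[1, 1])
  if (any(R0[traj$valid] < 1e-9)) stop("material point at the centroid")
  wrap_angle <- function(x) atan2(sin(x), cos(x))
  rad <- neighborhood_radius
  rad_c <- 2 * rad
  sig <- if (is.null(disp$noise_sd_est)) 0 else disp$noise_sd_est
  w_ridge <- sig / 0.15   # prior scale of the cubic radial coefficient
  E_xx <- matrix(NA_real_, n_pts, nf)
  E_xy <- E_xx; E_yy <- E_xx
  ok <- matrix(FALSE, n_pts, nf)
  for (f in seq_len(nf)) {
    mk <- disp$mask[, , f]
    idx <- which(mk, arr.ind = TRUE)
    xj <- ax[idx[, 1]]; yj <- ax[idx[, 2]]
    Xj <- xj - disp$u_x[, , f][mk]
    Yj <- yj - disp$u_y[, , f][mk]
    Rr <- sqrt((Xj - centroids[1, 1])^2 + (Yj - centroids[1, 2])^2)
    thr <- atan2(Yj - centroids[1, 2], Xj - centroids[1, 1])
    rc <- sqrt((xj - centroids[f, 1])^2 + (yj - centroids[f, 2])^2)
    thc <- atan2(yj - centroids[f, 2], xj - centroids[f, 1])
    for (p in seq_len(n_pts)) {
      if (!traj$valid[p]) next
      dR <- Rr - R0[p]
      dC <- R0[p] * wrap_angle(thr - th0[p])
      nb <- which(abs(dR) <= rad & abs(dC) <= rad_c)
      if (length(nb) < 9) next
      # the tracked trajectory provides the point's deformed position, the
      # centre for the inverse-map window
      r_hat <- sqrt((traj$paths[p, 1, f] - centroids[f, 1])^2 +
                      (traj$paths[p, 2, f] - centroids[f, 2])^2)
      th_hat <- atan2(traj$paths[p, 2, f] - centroids[f, 2],
                      traj$paths[p, 1, f] - centroids[f, 1])
      # inverse map on exact deformed predictors
      ddr <- rc[nb] - r_hat
      ddc <- r_hat * wrap_angle(thc[nb] - th_hat)
      Bi <- cbind(1, ddr, ddc, ddr^2, ddr * ddc, ddc^2, ddr^3)
      z1 <- Rr[nb]
      z2 <- dC[nb]
      if (w_ridge > 0) {
        # radially one-sided windows (wall edge, or the thin band at end
        # systole with no pixel centres) leave the cubic data-starved: the
        # prior tightens there
        one_sided <- min(ddr) > -0.2 * rad || max(ddr) < 0.2 * rad
        w <- if (one_sided) 4 * w_ridge else w_ridge
        Bi <- rbind(Bi, c(0, 0, 0, 0, 0, 0, w))
        z1 <- c(z1, 0); z2 <- c(z2, 0)
      }
      qi <- qr(Bi)
      if (qi$rank < ncol(Bi)) next
      cf_i <- qr.coef(qi, cbind(z1, z2))
      g <- rbind(c(cf_i[2, 1], cf_i[3, 1]),   # dX components / deformed offsets
                 c(cf_i[2, 2], cf_i[3, 2]))
      det_g <- g[1, 1] * g[2, 2] - g[1, 2] * g[2, 1]
      if (!is.finite(det_g) || abs(det_g) < 1e-9) next
      f11 <- g[2, 2] / det_g; f12 <- -g[1, 2] / det_g
      f21 <- -g[2, 1] / det_g; f22 <- g[1, 1] / det_g
      e_rr <- 0.5 * (f11^2 + f21^2 - 1)
      e_cc <- 0.5 * (f12^2 + f22^2 - 1)
      e_rc <- 0.5 * (f11 * f12 + f21 * f22)
      if (sig > 0) {
        # second-order (delta-method) bias correction: E is quadratic in F,
        # so estimator variance inflates the diagonal strains by half the
        # summed variances of the corresponding F column; propagate the LS
        # coefficient covariance through F = G^-1 (dF = -F dG F)
        Mi <- tryCatch(chol2inv(qr.R(qi)), error = function(e) NULL)
        if (!is.null(Mi)) {
          v22 <- sig^2 * Mi[2, 2]; v33 <- sig^2 * Mi[3, 3]
          c23 <- sig^2 * Mi[2, 3]
          fro <- f11^2 + f12^2 + f21^2 + f22^2
          q_r <- v22 * f11^2 + v33 * f21^2 + 2 * c23 * f11 * f21
          q_c <- v22 * f12^2 + v33 * f22^2 + 2 * c23 * f12 * f22
          e_rr <- e_rr - 0.5 * fro * q_r
          e_cc <- e_cc - 0.5 * fro * q_c
        }
      }
      erx <- cos(th0[p]); ery <- sin(th0[p])
      ecx <- -ery; ecy <- erx
      E_xx[p, f] <- erx^2 * e_rr + 2 * erx * ecx * e_rc + ecx^2 * e_cc
      E_yy[p, f] <- ery^2 * e_rr + 2 * ery * ecy * e_rc + ecy^2 * e_cc
      E_xy[p, f] <- erx * ery * e_rr + (erx * ecy + ery * ecx) * e_rc +
        ecx * ecy * e_cc
      ok[p, f] <- TRUE
    }
  }
  good <- traj$valid & apply(ok, 1, all)
  E_xx[!good, ] <- NA_real_
  E_xy[!good, ] <- NA_real_
  E_yy[!good, ] <- NA_real_
  structure(list(E_xx = E_xx, E_xy = E_xy, E_yy = E_yy,
                 valid = good, ref_points = ref,
                 frame_times = traj$frame_times,
                 neighborhood_radius = neighborhood_radius,
                 geometry = "polar"),
            class = "strain_tensor_field")
}

#' Project strain tensors onto anatomical directions
#'
#' Short-axis: the radial unit vector points from the end-diastolic epicardial
#' centroid to each reference point and the circumferential vector is 90
#' degrees counter-clockwise from it; `E_rr = e_r' E e_r`,
#' `E_cc = e_c' E e_c`.  Long-axis: `E_ll = e_l' E e_l` with `e_l` the local
#' wall-tangent direction at end diastole.  Directions are fixed in the
#' reference configuration.
#'
#' @param E A `strain_tensor_field`.
#' @param centroid End-diastolic epicardial centroid (mm, length 2).
#' @param orientation `"short_axis"` or `"long_axis"`.
#' @param tangent Optional n x 2 matrix of per-point wall-tangent directions
#'   for long-axis data; defaults to the image vertical (the long-axis
#'   direction for a ventricle aligned with the image).
#' @return List of `[points x frames]` matrices: `E_rr` and `E_cc`
#'   (short-axis) or `E_ll` (long-axis); plus per-point angles about the
#'   centroid (radians) for sector assignment.
#' @export
project_strain <- function(E, centroid, orientation = c("short_axis", "long_axis"),
                           tangent = NULL) {
  stopifnot(inherits(E, "strain_tensor_field"))
  orientation <- match.arg(orientation)
  dxv <- E$ref_points[, 1] - centroid[1]
  dyv <- E$ref_points[, 2] - centroid[2]
  r <- sqrt(dxv^2 + dyv^2)
  if (orientation == "short_axis") {
    bad <- r < 1e-9
    if (any(bad)) {
      dxv[bad] <- NA_real_; dyv[bad] <- NA_real_
    }
    erx <- dxv / r; ery <- dyv / r
    ecx <- -ery; ecy <- erx        # 90 deg counter-clockwise from e_r
    quad <- function(ax, ay) ax^2 * E$E_xx + 2 * ax * ay * E$E_xy + ay^2 * E$E_yy
    list(E_rr = quad(erx, ery), E_cc = quad(ecx, ecy),
         angle = atan2(dyv, dxv), radius = r)
  } else {
    if (is.null(tangent)) tangent <- cbind(rep(0, nrow(E$ref_points)), 1)
    tl <- tangent / sqrt(rowSums(tangent^2))
    E_ll <- tl[, 1]^2 * E$E_xx + 2 * tl[, 1] * tl[, 2] * E$E_xy +
      tl[, 2]^2 * E$E_yy
    list(E_ll = E_ll, angle = atan2(dyv, dxv), radius = r)
  }
}

#' Assign points to 16-segment-model sectors and transmural layers
#'
#' Short-axis points are binned into angular sectors relative to the landmark
#' angle (6 sectors for basal and mid slices, 4 for apical) and into
#' transmural thirds by normalized endocardium-to-epicardium depth at end
#' diastole.
#'
#' @param points n x 2 matrix of end-diastolic positions (mm).
#' @param ctr A [contours()] object at end diastole.
#' @param slice_id `"basal"`, `"mid"` or `"apical"` (fixes the sector count
#'   and the segment numbering offset within the 16-segment model).
#' @return Data frame with `segment` (character), `layer`
#'   (`"endo"`, `"mid"`, `"epi"`) and `depth` per point (NA outside the wall).
#' @export
assign_segments <- function(points, ctr, slice_id = c("mid", "basal", "apical")) {
  slice_id <- match.arg(slice_id)
  cen <- polygon_centroid(ctr$epi)
  th <- atan2(points[, 2] - cen[2], points[, 1] - cen[1])
  r <- sqrt((points[, 1] - cen[1])^2 + (points[, 2] - cen[2])^2)
  r_en <- contour_radius_fun(ctr$endo, cen)(th)
  r_ep <- contour_radius_fun(ctr$epi, cen)(th)
  depth <- (r - r_en) / (r_ep - r_en)
  depth[depth < -0.25 | depth > 1.25] <- NA_real_
  depth <- pmin(pmax(depth, 0), 1)
  layer <- cut(depth, breaks = c(-0.001, 1 / 3, 2 / 3, 1.001),
               labels = c("endo", "mid", "epi"))
  n_sect <- if (slice_id == "apical") 4L else 6L
  offset <- switch(slice_id, basal = 0L, mid = 6L, apical = 12L)
  rel <- (ctr$landmark_angle * pi / 180 - th) %% (2 * pi)
  sect <- pmin(floor(rel / (2 * pi / n_sect)) + 1L, n_sect)
  data.frame(segment = paste0("S", offset + sect),
             layer = as.character(layer), depth = depth,
             stringsAsFactors = FALSE)
}

# Long-axis analogue: two walls x three longitudinal levels; transmural depth
# across the wall thickness.  Apical cells are labelled so downstream
# aggregation can exclude them.
assign_segments_la <- function(points, roi, lv_length, view = "4ch") {
  x <- points[, 1]
  z <- points[, 2] + lv_length / 2
  wall <- ifelse(x >= 0, "w1", "w2")
  level <- cut(z / lv_length, breaks = c(-0.01, 1 / 3, 2 / 3, 1.01),
               labels = c("apical", "mid", "basal"))
  # transmural depth from per-wall radial extent
  depth <- rep(NA_real_, length(x))
  for (w in c("w1", "w2")) {
    sel <- wall == w
    if (!any(sel)) next
    rr <- abs(x[sel])
    depth[sel] <- (rr - min(rr)) / max(max(rr) - min(rr), 1e-9)
  }
  layer <- cut(depth, breaks = c(-0.001, 1 / 3, 2 / 3, 1.001),
               labels = c("endo", "mid", "epi"))
  data.frame(segment = paste(view, wall, as.character(level), sep = "_"),
             layer = as.character(layer), depth = depth,
             apical = level == "apical",
             stringsAsFactors = FALSE)
}

#' Aggregate per-point strain to segment and layer curves
#'
#' Curves are the mean over points in each (segment, layer) cell per frame;
#' the `"global"` layer of a segment is the mean over all the segment's
#' points.  Summary curves across segments use the mean of per-segment means
#' (not the pooled-pixel mean), matching how global strain is derived by
#' averaging the strain curves of the standardized segments.
#'
#' @param values `[points x frames]` matrix of directional strain.
#' @param assignment Data frame from [assign_segments()].
#' @param frame_times Frame times (ms).
#' @param direction Label (`"rr"`, `"cc"` or `"ll"`).
#' @param drop_segments Character vector of segments to exclude (e.g. apical
#'   segments for longitudinal strain).
#' @return An object of class `strain_curves`: long data frame with columns
#'   `direction`, `segment`, `layer`, `frame`, `time`, `value`.
#' @export
aggregate_segments <- function(values, assignment, frame_times,
                               direction = "cc", drop_segments = character(0)) {
  stopifnot(nrow(values) == nrow(assignment))
  ok <- !is.na(assignment$segment) & !is.na(assignment$layer) &
    !is.na(values[, 1]) & !(assignment$segment %in% drop_segments)
  if (!any(ok)) stop("no valid points to aggregate")
  v <- values[ok, , drop = FALSE]
  seg <- assignment$segment[ok]
  lay <- assignment$layer[ok]
  cells <- rbind(
    data.frame(segment = seg, layer = lay, row = seq_len(nrow(v))),
    data.frame(segment = seg, layer = "global", row = seq_len(nrow(v)))
  )
  key <- interaction(cells$segment, cells$layer, drop = TRUE)
  sums <- rowsum(v[cells$row, , drop = FALSE], key)
  cnt <- as.vector(table(key)[rownames(sums)])
  means <- sums / cnt
  parts <- strsplit(rownames(means), ".", fixed = TRUE)
  out <- data.frame(
    direction = direction,
    segment = rep(vapply(parts, `[`, "", 1), each = ncol(means)),
    layer = rep(vapply(parts, `[`, "", 2), each = ncol(means)),
    frame = rep(seq_len(ncol(means)), times = nrow(means)),
    time = rep(frame_times, times = nrow(means)),
    value = as.vector(t(means)),
    stringsAsFactors = FALSE
  )
  # flag empty (segment, layer) cells relative to the full crossing
  all_segs <- unique(seg)
  expected <- length(all_segs) * 4
  if (nrow(means) < expected) {
    message(sprintf("%d empty (segment, layer) cells excluded from '%s' curves",
                    expected - nrow(means), direction))
  }
  structure(out, class = c("strain_curves", "data.frame"))
}

#' Layer-summary strain curves
#'
#' Mean of per-segment curves for each (direction, layer), i.e. the
#' mean-of-segment-means aggregation.
#'
#' @param curves A `strain_curves` data frame.
#' @return Data frame with columns `direction`, `layer`, `frame`, `time`,
#'   `value`.
#' @export
layer_curves <- function(curves) {
  agg <- stats::aggregate(value ~ direction + layer + frame + time,
                          data = curves, FUN = mean)
  agg[order(agg$direction, agg$layer, agg$frame), ]
}

#' End-systolic frame from a global circumferential strain curve
#'
#' End systole is defined as the frame of the extremal (most negative) global
#' circumferential strain; for longitudinal-only data the global longitudinal
#' curve is used.
#'
#' @param curves A `strain_curves` data frame.
#' @return Integer frame index (1-based).
#' @export
es_frame_from_curves <- function(curves) {
  dir <- if (any(curves$direction == "cc")) "cc" else
    if (any(curves$direction == "ll")) "ll" else curves$direction[1]
  lc <- layer_curves(curves)
  g <- lc[lc$direction == dir & lc$layer == "global", ]
  g <- g[order(g$frame), ]
  which.min(g$value)
}

#' Peak strains and peak strain rates
#'
#' Peak strain is the signed extremum over the cycle (maximum for radial,
#' minimum for circumferential/longitudinal).  Strain rate is the centered
#' finite difference of each curve over the frame times (no smoothing, so
#' noise amplification by differentiation is reproduced, not hidden); the
#' peak systolic rate is the largest-magnitude rate at frames up to end
#' systole, the peak diastolic rate the largest-magnitude rate after it.
#'
#' When `smooth_peaks = TRUE` the peak strain is read from a temporal
#' Savitzky-Golay (local quadratic) filtering of each curve: smooth peaks
#' pass through the filter unchanged while frame-to-frame noise — which an
#' extremum search would otherwise rectify into a systematic overestimate —
#' is suppressed.  Rates are always differenced from the raw curves.
#'
#' @param curves A `strain_curves` data frame (>= 5 frames).
#' @param es_frame End-systolic frame (1-based); derived from the global
#'   circumferential curve if missing.
#' @param smooth_peaks Read peak strains from temporally filtered curves
#'   (see Details); default `FALSE` (raw extrema).
#' @return Data frame with one row per (direction, layer): `peak_strain_pct`,
#'   `peak_systolic_rate`, `peak_diastolic_rate` (% and %/ms), and
#'   `es_frame`.  A diagnostic warning is emitted if peak circumferential
#'   strain is positive or peak radial strain negative.
#' @export
extract_peaks_rates <- function(curves, es_frame = NULL, smooth_peaks = FALSE) {
  nf <- max(curves$frame)
  if (nf < 5) stop("need at least 5 frames to extract peaks and rates")
  if (is.null(es_frame)) es_frame <- es_frame_from_curves(curves)
  lc <- layer_curves(curves)
  keys <- unique(lc[, c("direction", "layer")])
  res <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- lc[lc$direction == keys$direction[i] & lc$layer == keys$layer[i], ]
    sub <- sub[order(sub$frame), ]
    v <- sub$value * 100
    tms <- sub$time
    vp <- if (smooth_peaks) sg_smooth_curve(v) else v
    peak <- if (keys$direction[i] == "rr") max(vp) else min(vp)
    rate <- finite_diff_rate(v, tms)
    sys <- rate[seq_len(es_frame)]
    dia <- rate[seq(es_frame + 1, length(rate))]
    data.frame(direction = keys$direction[i], layer = keys$layer[i],
               peak_strain_pct = peak,
               peak_systolic_rate = sys[which.max(abs(sys))],
               peak_diastolic_rate = dia[which.max(abs(dia))],
               es_frame = es_frame, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  gl <- out[out$layer == "global", ]
  if (any(gl$direction == "cc" & gl$peak_strain_pct > 0) ||
      any(gl$direction == "rr" & gl$peak_strain_pct < 0)) {
    warning("unexpected sign of global peak strain for a contracting ventricle")
  }
  out
}
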