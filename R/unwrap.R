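#' Quality map for phase unwrapping
#'
#' Quality is the inverse local variance of the wrapped phase gradients in a
#' 3 x 3 window (pixels whose neighbourhood wraps coherently rank highest);
#' standard guidance for region-growing unwrappers.
#'
#' @param phase Wrapped phase matrix (radians).
#' @param mask Logical matrix of pixels with signal.
#' @return Numeric matrix of quality values (higher is better; NA outside the
#'   mask).
#' @export
phase_quality <- function(phase, mask) {
  pm <- phase
  pm[!mask] <- NA_real_
  gx <- wrap_phase(shift_matrix(pm, -1, 0) - pm)
  gy <- wrap_phase(shift_matrix(pm, 0, -1) - pm)
  local_var <- function(g) {
    s <- matrix(0, nrow(g), ncol(g)); s2 <- s; cnt <- s
    for (di in -1:1) for (dj in -1:1) {
      v <- shift_matrix(g, di, dj)
      ok <- !is.na(v)
      s[ok] <- s[ok] + v[ok]
      s2[ok] <- s2[ok] + v[ok]^2
      cnt <- cnt + ok
    }
    out <- matrix(NA_real_, nrow(g), ncol(g))
    ok <- cnt > 1
    out[ok] <- pmax(s2[ok] / cnt[ok] - (s[ok] / cnt[ok])^2, 0)
    out
  }
  v <- local_var(gx) + local_var(gy)
  v[is.na(v)] <- 0
  q <- 1 / (1e-6 + v)
  q[!mask] <- NA_real_
  q
}

#' Unwrap a single wrapped phase image
#'
#' Quality-guided region growing: each 4-connected component of the mask is
#' seeded at its highest-quality pixel and grown in order of decreasing
#' quality, adding the 2*pi multiple that keeps each new pixel closest to the
#' solved neighbour it was reached from.  The output minus the input is an
#' integer multiple of 2*pi at every masked pixel.
#'
#' @param phase Wrapped phase matrix, values in (-pi, pi].
#' @param mask Logical matrix; must be nonempty.
#' @param quality Optional quality map; computed by [phase_quality()] if
#'   missing.
#' @return Matrix of unwrapped phase (NA outside the mask).  Each mask
#'   component carries an arbitrary global 2*pi offset; see [unwrap_series()]
#'   for how offsets are resolved across frames.
#' @export
unwrap_phase <- function(phase, mask, quality = NULL) {
  stopifnot(is.matrix(phase), is.logical(mask), all(dim(mask) == dim(phase)))
  if (!any(mask)) stop("empty mask: nothing to unwrap")
  if (is.null(quality)) quality <- phase_quality(phase, mask)
  q <- quality
  q[is.na(q)] <- -Inf
  unwrap_qg_cpp(phase, mask, q)
}

# Resolve the global 2*pi offset of each mask component.  At the first frame
# displacements are small, so the offset minimizing the median |phase| is
# chosen; later frames are anchored to the previous frame's unwrapped phase
# (temporal continuity).
resolve_offsets <- function(unw, mask, prev = NULL) {
  lab <- label_components_cpp(mask)
  for (cc in seq_len(max(lab))) {
    idx <- lab == cc
    k <- NA_real_
    if (!is.null(prev)) {
      common <- idx & !is.na(prev)
      if (sum(common) >= 5) {
        k <- round(stats::median(prev[common] - unw[common]) / (2 * pi))
      }
    }
    if (is.na(k)) k <- -round(stats::median(unw[idx]) / (2 * pi))
    unw[idx] <- unw[idx] + 2 * pi * k
  }
  unw
}

# Repair isolated 2*pi unwrapping errors: a pixel whose unwrapped phase
# differs from the median of its masked 4-neighbours by more than pi is
# shifted by the integer number of cycles that brings it closest.
repair_phase_outliers <- function(u, mask, passes = 2L) {
  for (p in seq_len(passes)) {
    med <- local_masked_median(u, mask)
    d <- u - med
    bad <- mask & !is.na(d) & abs(d) > pi
    if (!any(bad)) break
    u[bad] <- u[bad] - 2 * pi * round(d[bad] / (2 * pi))
  }
  u
}

# Median over the masked 4-neighbours of each pixel (NA if none); with all
# four neighbours present this is the trimmed mean of the middle two.
local_masked_median <- function(u, mask) {
  um <- u
  um[!mask] <- NA_real_
  n1 <- shift_matrix(um, 1, 0); n2 <- shift_matrix(um, -1, 0)
  n3 <- shift_matrix(um, 0, 1); n4 <- shift_matrix(um, 0, -1)
  cnt <- (!is.na(n1)) + (!is.na(n2)) + (!is.na(n3)) + (!is.na(n4))
  z <- function(m) ifelse(is.na(m), 0, m)
  rs <- z(n1) + z(n2) + z(n3) + z(n4)
  rmin <- pmin(n1, n2, n3, n4, na.rm = TRUE)
  rmax <- pmax(n1, n2, n3, n4, na.rm = TRUE)
  med <- ifelse(cnt == 4, (rs - rmin - rmax) / 2,
                ifelse(cnt > 0, rs / cnt, NA_real_))
  matrix(med, nrow(u), ncol(u))
}

#' Convert unwrapped phase to displacement
#'
#' The DENSE encoding relation: displacement `u = phase / (2*pi*k_e)`, with
#' positive phase meaning displacement toward the positive encoding axis.
#'
#' @param unwrapped Unwrapped phase (radians), any shape.
#' @param k_e Displacement encoding frequency (cycles/mm), > 0.
#' @return Displacement in mm, same shape as `unwrapped`.
#' @export
phase_to_displacement <- function(unwrapped, k_e) {
  stopifnot(is.numeric(k_e), length(k_e) == 1, k_e > 0)
  unwrapped / (2 * pi * k_e)
}

#' Unwrap a full DENSE series and derive the displacement field
#'
#' Runs spatial quality-guided unwrapping per frame and encoding direction,
#' resolves each component's global 2*pi offset (minimal displacement at the
#' first frame, temporal continuity thereafter), then applies a pixel-wise
#' temporal continuity pass that overrides residual spatial ambiguities.
#'
#' @param series A `dense_series` (see [render_dense_series()]).
#' @param masks List of per-frame logical myocardial masks; derived from the
#'   magnitude images via [segment_series()] if missing.
#' @param displacement_cap Physiologic sanity bound on `|u|` (mm);
#'   violations are flagged with a warning, never clipped.
#' @param temporal_smooth Apply a pixel-wise temporal quadratic
#'   (Savitzky-Golay) filter to the displacement stacks.  The default
#'   (`NULL`) turns it on only when the estimated per-pixel noise exceeds
#'   0.02 rad of phase noise, so noiseless data pass through untouched.
#' @return An object of class `displacement_field`: arrays `u_x`, `u_y`
#'   `[x, y, frame]` in mm (NA outside the mask), `mask`, `pixel_spacing`,
#'   `phase_x`, `phase_y` (unwrapped), and the estimated per-pixel noise
#'   `noise_sd_est` (mm).
#' @export
unwrap_series <- function(series, masks = NULL, displacement_cap = 3,
                          temporal_smooth = NULL) {
  stopifnot(inherits(series, "dense_series"))
  if (is.null(masks)) masks <- segment_series(series)
  nf <- dim(series$phase_x)[3]
  stopifnot(length(masks) == nf)
  dims <- dim(series$phase_x)
  # work on the mask bounding box; the rest of the image is noise
  bb <- mask_bbox(Reduce(`|`, masks), margin = 3L)
  ri <- bb[1]:bb[2]; ci <- bb[3]:bb[4]
  out <- list(phase_x = array(NA_real_, dims), phase_y = array(NA_real_, dims))
  for (comp in c("phase_x", "phase_y")) {
    prev <- NULL
    for (f in seq_len(nf)) {
      ph <- series[[comp]][ri, ci, f]
      m <- masks[[f]][ri, ci]
      u <- unwrap_phase(ph, m)
      u <- resolve_offsets(u, m, prev)
      if (!is.null(prev)) {
        # temporal pass: favour pixel-wise continuity across frames
        common <- m & !is.na(prev)
        jump <- round((prev[common] - u[common]) / (2 * pi))
        u[common] <- u[common] + 2 * pi * jump
      }
      u <- repair_phase_outliers(u, m)
      out[[comp]][ri, ci, f] <- u
      prev <- u
    }
  }
  u_x <- phase_to_displacement(out$phase_x, series$k_e)
  u_y <- phase_to_displacement(out$phase_y, series$k_e)
  mask_tmp <- array(FALSE, dims)
  for (f in seq_len(nf)) mask_tmp[, , f] <- masks[[f]]
  noise_est <- estimate_field_noise(list(u_x = u_x, u_y = u_y,
                                         mask = mask_tmp))
  if (is.null(temporal_smooth)) {
    # the Eulerian field evolves smoothly over the cycle: with material
    # pixel noise, a temporal quadratic (Savitzky-Golay) filter halves it
    # without biasing smooth motion; noiseless data are left untouched
    temporal_smooth <- noise_est > 0.02 / (2 * pi * series$k_e)
  }
  if (temporal_smooth && nf >= 5) {
    u_x <- sg_smooth_stack(u_x, mask_tmp)
    u_y <- sg_smooth_stack(u_y, mask_tmp)
  }
  umax <- max(abs(c(u_x, u_y)), na.rm = TRUE)
  if (umax > displacement_cap) {
    warning(sprintf("displacement magnitude %.2f mm exceeds the %.1f mm sanity cap; check unwrapping",
                    umax, displacement_cap))
  }
  structure(list(u_x = u_x, u_y = u_y, mask = mask_tmp,
                 pixel_spacing = series$pixel_spacing,
                 phase_x = out$phase_x, phase_y = out$phase_y,
                 frame_times = series$frame_times, k_e = series$k_e,
                 noise_sd_est = noise_est,
                 temporally_smoothed = temporal_smooth),
            class = "displacement_field")
}

# Pixel-wise temporal Savitzky-Golay (quadratic) filter of a displacement
# stack; a pixel is filtered at frame f only if it is masked throughout the
# window, so wall passage does not bleed background into the field.
sg_smooth_stack <- function(arr, mask, half = 3L) {
  d <- dim(arr)
  nf <- d[3]
  flat <- matrix(arr, d[1] * d[2], nf)
  msk <- matrix(mask, d[1] * d[2], nf)
  out <- flat
  for (f in seq_len(nf)) {
    lo <- max(1L, f - half); hi <- min(nf, f + half)
    win <- lo:hi
    if (length(win) <= 3L) next
    x <- win - f
    P <- solve(crossprod(cbind(1, x, x^2)), t(cbind(1, x, x^2)))[1, ]
    rows <- which(msk[, f] & rowSums(msk[, win, drop = FALSE]) == length(win))
    if (length(rows) == 0) next
    out[rows, f] <- flat[rows, win, drop = FALSE] %*% P
  }
  array(out, d)
}

#' Segment the myocardium on the magnitude images
#'
#' Motion-guided magnitude segmentation: each frame's mask is the pixels above
#' an automatic intensity threshold, restricted to a small dilation of the
#' previous frame's mask (frame 1 uses the supplied region of interest), and
#' reduced to the largest connected component.
#'
#' @param series A `dense_series`.
#' @param roi Optional logical matrix restricting frame 1 (e.g. rasterized
#'   initial contours); defaults to the whole image.
#' @param dilate Guidance dilation in pixels between consecutive frames.
#' @return List of per-frame logical masks.
#' @export
segment_series <- function(series, roi = NULL, dilate = 2L) {
  nf <- dim(series$magnitude)[3]
  masks <- vector("list", nf)
  prev <- NULL
  for (f in seq_len(nf)) {
    m <- series$magnitude[, , f]
    thr <- 0.5 * (stats::median(m) + stats::quantile(m, 0.999, names = FALSE))
    cand <- m > thr
    guide <- if (f == 1) roi else prev
    if (!is.null(guide)) cand <- cand & dilate_mask(guide, dilate)
    if (!any(cand)) stop("segmentation produced an empty mask at frame ", f)
    masks[[f]] <- largest_component(cand)
    prev <- masks[[f]]
  }
  masks
}
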