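#' Slice twist versus time
#'
#' For each material point, the signed angle between the radial line from the
#' end-diastolic centroid to the point's reference position and the line from
#' the current centroid to its current position; slice twist is the circular
#' mean over all valid myocardial points.  Positive angles are
#' counter-clockwise in the standard apex-to-base viewing orientation.
#' Using the per-frame centroid (from the propagated epicardial contour)
#' cancels bulk in-plane translation.
#'
#' @param traj A `material_trajectories` object (>= 10 valid points).
#' @param centroids Frame x 2 matrix of per-frame LV centroids (mm), e.g.
#'   from [propagate_contours()].
#' @return Numeric vector of twist angles (degrees) per frame; 0 at frame 1
#'   by construction.
#' @export
compute_twist <- function(traj, centroids) {
  stopifnot(inherits(traj, "material_trajectories"))
  nf <- dim(traj$paths)[3]
  stopifnot(nrow(centroids) == nf)
  ok <- traj$valid
  if (sum(ok) < 10) stop("need at least 10 valid material points for twist")
  rx <- traj$ref_points[ok, 1] - centroids[1, 1]
  ry <- traj$ref_points[ok, 2] - centroids[1, 2]
  twist <- numeric(nf)
  for (f in seq_len(nf)) {
    cx <- traj$paths[ok, 1, f] - centroids[f, 1]
    cy <- traj$paths[ok, 2, f] - centroids[f, 2]
    ang <- atan2(rx * cy - ry * cx, rx * cx + ry * cy) * 180 / pi
    twist[f] <- circular_mean_deg(ang)
  }
  twist
}

#' Torsion from basal and apical twist curves
#'
#' Torsion is the apical-minus-basal twist difference normalized by the
#' end-diastolic long-axis epicardial length (conventionally the mean of the
#' 2-chamber and 4-chamber measurements).
#'
#' @param twist_basal,twist_apical Twist curves (degrees) on a common frame
#'   grid.
#' @param lv_length_ed End-diastolic long-axis epicardial length in cm, or a
#'   vector of measurements (e.g. the two long-axis views) that is averaged.
#' @return Torsion (degrees/cm) per frame.
#' @export
compute_torsion <- function(twist_basal, twist_apical, lv_length_ed) {
  if (length(twist_basal) != length(twist_apical)) {
    stop("basal and apical twist curves must share the same frame grid")
  }
  L <- mean(lv_length_ed)
  stopifnot(L > 0)
  (twist_apical - twist_basal) / L
}

#' Peak systolic and diastolic rates of twist or torsion curves
#'
#' Centered finite differences over the frame times; the peak systolic rate
#' is the largest-magnitude rate at frames up to end systole, the peak
#' diastolic rate the largest-magnitude rate after it (same machinery as the
#' strain rates).
#'
#' @param curve Twist (deg) or torsion (deg/cm) per frame.
#' @param frame_times Frame times (ms).
#' @param es_frame End-systolic frame (1-based), strictly inside the cycle.
#' @return List with `peak_systolic_rate` and `peak_diastolic_rate`
#'   (deg/ms or deg/cm/ms).
#' @export
twist_torsion_rates <- function(curve, frame_times, es_frame) {
  n <- length(curve)
  stopifnot(length(frame_times) == n, es_frame >= 1, es_frame < n)
  rate <- finite_diff_rate(curve, frame_times)
  sys <- rate[seq_len(es_frame)]
  dia <- rate[seq(es_frame + 1, n)]
  list(peak_systolic_rate = sys[which.max(abs(sys))],
       peak_diastolic_rate = dia[which.max(abs(dia))])
}
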