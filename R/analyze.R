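#' Analysis parameters
#'
#' @param neighborhood_radius Strain neighbourhood radius (mm).
#' @param n_sectors Angular sectors for the synchrony indices.
#' @param displacement_cap Sanity bound on displacement magnitude (mm).
#' @param sqrt_cure If `TRUE`, report the square-root variant of the
#'   uniformity ratio.
#' @return An `analysis_params` object.
#' @export
analysis_params <- function(neighborhood_radius = 0.75, n_sectors = 24,
                            displacement_cap = 3, sqrt_cure = FALSE) {
  structure(list(neighborhood_radius = neighborhood_radius,
                 n_sectors = n_sectors,
                 displacement_cap = displacement_cap,
                 sqrt_cure = sqrt_cure),
            class = "analysis_params")
}

#' Analyze a single DENSE slice
#'
#' Full single-slice pipeline: magnitude segmentation, phase unwrapping,
#' Eulerian-to-Lagrangian tracking, strain tensors, directional projection,
#' segment/layer aggregation and (for short-axis slices) twist.
#'
#' @param series A `dense_series`.
#' @param init_contours A [contours()] object at end diastole (required for
#'   short-axis slices; ignored for long-axis).
#' @param params An [analysis_params()].
#' @return A list with `curves` (strain curves), `es_frame`, per-point
#'   projected strain (`proj`), and for short-axis slices `twist` (deg per
#'   frame) and `centroids`; long-axis slices add the measured end-diastolic
#'   epicardial length `lv_length_mm`.
#' @export
analyze_dense_series <- function(series, init_contours = NULL,
                                 params = analysis_params()) {
  stopifnot(inherits(series, "dense_series"))
  ft <- series$frame_times
  if (series$orientation == "short_axis") {
    if (is.null(init_contours)) {
      stop("short-axis analysis requires initial end-diastolic contours")
    }
    n <- dim(series$magnitude)[1]
    roi <- rasterize_annulus(init_contours, n, series$pixel_spacing)
    masks <- segment_series(series, roi = roi)
    disp <- unwrap_series(series, masks, params$displacement_cap)
    traj <- build_trajectories(disp, roi = roi & masks[[1]])
    prop <- propagate_contours(init_contours, disp)
    E <- compute_strain(traj, params$neighborhood_radius,
                        geometry = "polar", centroids = prop$centroids)
    proj <- project_strain(E, prop$centroids[1, ], "short_axis")
    assignment <- assign_segments(traj$ref_points, init_contours,
                                  slice_id = series$slice_id)
    curves <- rbind(
      aggregate_segments(proj$E_cc, assignment, ft, "cc"),
      aggregate_segments(proj$E_rr, assignment, ft, "rr")
    )
    class(curves) <- c("strain_curves", "data.frame")
    es <- es_frame_from_curves(curves)
    twist <- compute_twist(traj, prop$centroids)
    list(slice_id = series$slice_id, orientation = "short_axis",
         curves = curves, es_frame = es, twist = twist,
         proj = proj, assignment = assignment,
         centroids = prop$centroids, frame_times = ft,
         n_frames = length(ft),
         noisy = isTRUE(disp$temporally_smoothed))
  } else {
    masks <- segment_series(series)
    disp <- unwrap_series(series, masks, params$displacement_cap)
    traj <- build_trajectories(disp, roi = masks[[1]])
    E <- compute_strain(traj, params$neighborhood_radius)
    cen <- colMeans(traj$ref_points)
    proj <- project_strain(E, cen, "long_axis")
    dx <- series$pixel_spacing
    lv_length <- diff(range(traj$ref_points[, 2])) + dx
    assignment <- assign_segments_la(traj$ref_points, masks[[1]],
                                     lv_length = lv_length,
                                     view = series$slice_id)
    apical_segs <- unique(assignment$segment[assignment$apical])
    curves <- aggregate_segments(proj$E_ll, assignment, ft, "ll",
                                 drop_segments = apical_segs)
    es <- es_frame_from_curves(curves)
    list(slice_id = series$slice_id, orientation = "long_axis",
         curves = curves, es_frame = es, proj = proj,
         assignment = assignment, lv_length_mm = lv_length,
         frame_times = ft, n_frames = length(ft),
         noisy = isTRUE(disp$temporally_smoothed))
  }
}

#' Analyze one animal's full DENSE study
#'
#' Combines the per-slice analyses of the three short-axis slices (and any
#' long-axis views) into the scalar endpoints reported for a study: peak
#' strains and strain rates per direction and transmural layer, end-systolic
#' twist and twist rates per slice, peak torsion and torsion rates, and the
#' CURE/RURE synchrony indices over the total, systolic and diastolic
#' windows.  End systole is the rounded mean of the per-short-axis-slice
#' circumferential strain extremum frames.
#'
#' @param series_list Named list of `dense_series` (names are slice ids).
#' @param contours_list Named list of [contours()] for the short-axis slices.
#' @param params An [analysis_params()].
#' @param lv_length_mm Optional end-diastolic epicardial length (mm) used for
#'   torsion when no long-axis views are supplied.
#' @return A list with `endpoints` (data frame `endpoint`, `value`),
#'   `es_frame`, and the per-slice analyses (`slices`).
#' @export
analyze_mouse_study <- function(series_list, contours_list,
                                params = analysis_params(),
                                lv_length_mm = NULL) {
  sa_ids <- names(series_list)[vapply(series_list, function(s)
    s$orientation == "short_axis", logical(1))]
  la_ids <- setdiff(names(series_list), sa_ids)
  res <- list()
  for (id in names(series_list)) {
    res[[id]] <- analyze_dense_series(series_list[[id]],
                                      contours_list[[id]], params)
  }
  nf <- res[[1]]$n_frames
  ft <- res[[1]]$frame_times
  es <- round(mean(vapply(res[sa_ids], `[[`, numeric(1), "es_frame")))
  es <- max(2, min(es, nf - 1))
  ep <- list()
  add <- function(name, value) ep[[length(ep) + 1]] <<-
    data.frame(endpoint = name, value = value, stringsAsFactors = FALSE)

  noisy <- any(vapply(res, function(r) isTRUE(r$noisy), logical(1)))
  if (length(sa_ids) > 0) {
    sa_curves <- do.call(rbind, lapply(res[sa_ids], `[[`, "curves"))
    pk <- extract_peaks_rates(sa_curves, es_frame = es, smooth_peaks = noisy)
    for (i in seq_len(nrow(pk))) {
      key <- paste0(pk$direction[i], "_", pk$layer[i])
      add(paste0("peak_", key), pk$peak_strain_pct[i])
      add(paste0("sys_rate_", key), pk$peak_systolic_rate[i])
      add(paste0("dia_rate_", key), pk$peak_diastolic_rate[i])
    }
    for (id in sa_ids) {
      tw <- res[[id]]$twist
      add(paste0("es_twist_", id), tw[es])
      rates <- twist_torsion_rates(tw, ft, es)
      add(paste0("sys_twist_rate_", id), rates$peak_systolic_rate)
      add(paste0("dia_twist_rate_", id), rates$peak_diastolic_rate)
    }
    if (all(c("basal", "apical") %in% sa_ids)) {
      if (length(la_ids) > 0) {
        L_mm <- mean(vapply(res[la_ids], `[[`, numeric(1), "lv_length_mm"))
      } else if (!is.null(lv_length_mm)) {
        L_mm <- lv_length_mm
      } else {
        L_mm <- series_list[[sa_ids[1]]]$lv_length_ed
      }
      tors <- compute_torsion(res[["basal"]]$twist, res[["apical"]]$twist,
                              L_mm / 10)
      add("peak_torsion", tors[which.max(abs(tors))])
      trates <- twist_torsion_rates(tors, ft, es)
      add("sys_torsion_rate", trates$peak_systolic_rate)
      add("dia_torsion_rate", trates$peak_diastolic_rate)
    }
    wins <- synchrony_windows(es, nf)
    cc_list <- lapply(res[sa_ids], function(r) r$proj$E_cc)
    rr_list <- lapply(res[sa_ids], function(r) r$proj$E_rr)
    ang_list <- lapply(res[sa_ids], function(r) r$proj$angle)
    for (w in names(wins)) {
      add(paste0("cure_", w),
          uniformity_ratio(cc_list, ang_list, params$n_sectors, wins[[w]],
                           params$sqrt_cure))
      add(paste0("rure_", w),
          uniformity_ratio(rr_list, ang_list, params$n_sectors, wins[[w]],
                           params$sqrt_cure))
    }
  }
  if (length(la_ids) > 0) {
    ll_curves <- do.call(rbind, lapply(res[la_ids], `[[`, "curves"))
    class(ll_curves) <- c("strain_curves", "data.frame")
    pk <- extract_peaks_rates(ll_curves, es_frame = es, smooth_peaks = noisy)
    for (i in seq_len(nrow(pk))) {
      key <- paste0("ll_", pk$layer[i])
      add(paste0("peak_", key), pk$peak_strain_pct[i])
      add(paste0("sys_rate_", key), pk$peak_systolic_rate[i])
      add(paste0("dia_rate_", key), pk$peak_diastolic_rate[i])
    }
  }
  list(endpoints = do.call(rbind, ep), es_frame = es, slices = res)
}

#' Sensitivity of endpoints to initial contour placement
#'
#' Re-analyzes a short-axis slice with the initial contours perturbed by a
#' given amount and reports the change in the global peak strains — the
#' mechanism behind inter-observer variance.  Contour perturbations are never
#' silently absorbed; this diagnostic quantifies them.
#'
#' @param series A short-axis `dense_series`.
#' @param init_contours Baseline [contours()].
#' @param sd Radial contour perturbation (mm); default one pixel.
#' @param rng_seed Seed for the perturbation.
#' @param params An [analysis_params()].
#' @return Data frame with baseline and perturbed global peak strains and
#'   their differences.
#' @export
contour_sensitivity <- function(series, init_contours, sd = NULL,
                                rng_seed = 1, params = analysis_params()) {
  if (is.null(sd)) sd <- series$pixel_spacing
  base <- analyze_dense_series(series, init_contours, params)
  pert <- analyze_dense_series(series,
                               perturb_contours(init_contours, sd,
                                                rng_seed = rng_seed),
                               params)
  pk_b <- extract_peaks_rates(base$curves, base$es_frame,
                              smooth_peaks = isTRUE(base$noisy))
  pk_p <- extract_peaks_rates(pert$curves, pert$es_frame,
                              smooth_peaks = isTRUE(pert$noisy))
  gb <- pk_b[pk_b$layer == "global", c("direction", "peak_strain_pct")]
  gp <- pk_p[pk_p$layer == "global", c("direction", "peak_strain_pct")]
  m <- merge(gb, gp, by = "direction", suffixes = c("_baseline", "_perturbed"))
  m$delta <- m$peak_strain_pct_perturbed - m$peak_strain_pct_baseline
  m
}
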