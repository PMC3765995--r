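#' Write a DENSE series to NIfTI stacks with a JSON sidecar
#'
#' One NIfTI file per stack (`magnitude`, `phase_x`, `phase_y`) plus a JSON
#' sidecar carrying the acquisition metadata (encoding frequency, frame
#' times, slice identity and position, pixel spacing).
#'
#' @param series A `dense_series`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix; defaults to the slice id.
#' @return Invisibly, the sidecar path.
#' @export
write_dense_series <- function(series, dir, prefix = series$slice_id) {
  stopifnot(inherits(series, "dense_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (stack in c("magnitude", "phase_x", "phase_y")) {
    img <- RNifti::asNifti(series[[stack]],
                           pixdim = c(series$pixel_spacing,
                                      series$pixel_spacing, 1))
    RNifti::writeNifti(img, file.path(dir, paste0(prefix, "_", stack, ".nii.gz")))
  }
  sidecar <- list(slice_id = series$slice_id,
                  orientation = series$orientation,
                  slice_position = series$slice_position,
                  k_e = series$k_e,
                  pixel_spacing = series$pixel_spacing,
                  frame_times = series$frame_times,
                  fov = series$fov,
                  landmark_angle = series$landmark_angle,
                  lv_length_ed = series$lv_length_ed)
  path <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a DENSE series written by [write_dense_series()]
#'
#' @param dir Directory containing the stacks and sidecar.
#' @param prefix File name prefix.
#' @return A `dense_series`.
#' @export
read_dense_series <- function(dir, prefix) {
  path <- file.path(dir, paste0(prefix, ".json"))
  if (!file.exists(path)) stop("missing sidecar: ", path)
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  stacks <- list()
  for (stack in c("magnitude", "phase_x", "phase_y")) {
    f <- file.path(dir, paste0(prefix, "_", stack, ".nii.gz"))
    if (!file.exists(f)) stop("missing input stack: ", f)
    img <- as.array(RNifti::readNifti(f))
    stacks[[stack]] <- array(as.numeric(img), dim(img))
  }
  structure(c(stacks, meta[c("pixel_spacing", "frame_times", "slice_id",
                             "slice_position", "orientation", "k_e", "fov",
                             "landmark_angle", "lv_length_ed")]),
            class = "dense_series")
}

#' Write contours to CSV polylines
#'
#' Long format: one row per vertex with columns `boundary`
#' (`"endo"`/`"epi"`), `x_mm`, `y_mm`, `frame`.
#'
#' @param ctr A [contours()] object or a list of them (one per frame).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_contours_csv <- function(ctr, path) {
  if (inherits(ctr, "contours")) ctr <- list(ctr)
  rows <- lapply(ctr, function(cc) {
    rbind(data.frame(boundary = "endo", x_mm = cc$endo[, 1],
                     y_mm = cc$endo[, 2], frame = cc$frame),
          data.frame(boundary = "epi", x_mm = cc$epi[, 1],
                     y_mm = cc$epi[, 2], frame = cc$frame))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write material trajectories to long-format CSV
#'
#' One row per (point, frame): `point_id`, `frame`, `time_ms`, `x_mm`,
#' `y_mm`, `valid`.
#'
#' @param traj A `material_trajectories` object.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_trajectories_csv <- function(traj, path) {
  stopifnot(inherits(traj, "material_trajectories"))
  nf <- dim(traj$paths)[3]
  n <- nrow(traj$ref_points)
  df <- data.frame(
    point_id = rep(seq_len(n), times = nf),
    frame = rep(seq_len(nf), each = n),
    time_ms = rep(traj$frame_times, each = n),
    x_mm = as.vector(traj$paths[, 1, ]),
    y_mm = as.vector(traj$paths[, 2, ]),
    valid = rep(traj$valid, times = nf))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Write the study result CSVs and the run manifest.
write_study_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$endpoints, file.path(out_dir, "endpoints.csv"),
                   row.names = FALSE)
  utils::write.csv(res$report, file.path(out_dir, "reproducibility_report.csv"),
                   row.names = FALSE)
  utils::write.csv(res$truth, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(res$params, file.path(out_dir, "cohort_parameters.csv"),
                   row.names = FALSE)
  manifest <- list(
    package = "densecmr",
    version = as.character(utils::packageVersion("densecmr")),
    seed = res$spec$seed,
    n_mice = res$spec$n_mice,
    slices = res$spec$slices,
    acquisition = res$spec$acquisition[c("matrix_size", "fov", "n_frames",
                                         "frame_interval", "k_e", "noise_sd")],
    inter_test_slice_jitter_sd = res$spec$inter_test_slice_jitter_sd,
    observer_contour_jitter_sd = res$spec$observer_contour_jitter_sd,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Build a cohort specification from a YAML configuration file
#'
#' Recognized keys mirror the [cohort_spec()] and [acquisition_spec()]
#' arguments (`n_mice`, `inter_test_slice_jitter_sd`, `inter_test_noise_sd`,
#' `observer_contour_jitter_sd`, `seed`, `slices`, and an `acquisition`
#' block).
#'
#' @param path Path to a YAML file.
#' @return A `cohort_spec`.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  acq_args <- cfg$acquisition
  acq <- if (is.null(acq_args)) acquisition_spec() else
    do.call(acquisition_spec, acq_args)
  args <- cfg[setdiff(names(cfg), c("acquisition", "n_normal", "n_depressed"))]
  unknown <- setdiff(names(args), names(formals(cohort_spec)))
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  if (is.null(args$groups)) {
    n_mice <- if (is.null(args$n_mice)) formals(cohort_spec)$n_mice else args$n_mice
    n_norm <- if (is.null(cfg$n_normal)) ceiling(n_mice / 2) else cfg$n_normal
    n_dep <- if (is.null(cfg$n_depressed)) n_mice - n_norm else cfg$n_depressed
    args$groups <- cohort_groups(n_norm, n_dep)
  }
  do.call(cohort_spec, c(args, list(acquisition = acq)))
}
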