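#' Virtual cohort specification
#'
#' Describes a reproducibility study design: a cohort of animals drawn from
#' parameter distributions, imaged on two days (same heart, independent noise
#' and slice-position jitter) and re-analyzed by a second observer (same
#' day-1 images, perturbed initial contours).
#'
#' @param n_mice Number of animals (>= 2); must equal the sum of group sizes.
#' @param groups List of group definitions; see [cohort_groups()].
#' @param inter_test_slice_jitter_sd SD of the day-2 short-axis
#'   slice-position error (mm).
#' @param inter_test_noise_sd Phase noise SD per acquisition (radians).
#' @param observer_contour_jitter_sd SD of the second observer's radial
#'   contour perturbation (mm).
#' @param acquisition An [acquisition_spec()]; its `noise_sd` is set from
#'   `inter_test_noise_sd`.
#' @param slices Character vector of slices to acquire.
#' @param twist_profile Optional twist profile shared by all animals
#'   (scaled per animal); defaults to the [deformation_model()] default.
#' @param seed Integer seed making the whole cohort a pure function of this
#'   specification.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_mice = 9, groups = cohort_groups(),
                        inter_test_slice_jitter_sd = 0.3,
                        inter_test_noise_sd = 0.1,
                        observer_contour_jitter_sd = 0.125,
                        acquisition = acquisition_spec(),
                        slices = c("basal", "mid", "apical", "4ch", "2ch"),
                        twist_profile = NULL,
                        seed = 1) {
  stopifnot(n_mice >= 2,
            inter_test_slice_jitter_sd >= 0,
            inter_test_noise_sd >= 0,
            observer_contour_jitter_sd >= 0)
  if (sum(vapply(groups, `[[`, numeric(1), "n")) != n_mice) {
    stop("group sizes must sum to n_mice")
  }
  acquisition$noise_sd <- inter_test_noise_sd
  structure(list(n_mice = as.integer(n_mice), groups = groups,
                 inter_test_slice_jitter_sd = inter_test_slice_jitter_sd,
                 inter_test_noise_sd = inter_test_noise_sd,
                 observer_contour_jitter_sd = observer_contour_jitter_sd,
                 acquisition = acquisition, slices = slices,
                 twist_profile = twist_profile,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default cohort groups
#'
#' Five normal animals and four with depressed function (lower contraction
#' and twist), mirroring a normal-versus-obese study design.  Each entry
#' gives the mean and SD of the per-animal parameter draws.
#'
#' @param n_normal,n_depressed Group sizes.
#' @return List of group definitions.
#' @export
cohort_groups <- function(n_normal = 5, n_depressed = 4) {
  list(
    normal = list(n = n_normal,
                  peak_circ_shortening = c(0.18, 0.015),
                  twist_scale = c(1.0, 0.10),
                  long_shortening = c(0.12, 0.01)),
    depressed = list(n = n_depressed,
                     peak_circ_shortening = c(0.13, 0.015),
                     twist_scale = c(0.7, 0.10),
                     long_shortening = c(0.10, 0.01))
  )
}

# Draw all per-animal parameters and sub-seeds from the cohort seed, in a
# fixed order, so the cohort is a pure function of (spec, seed).
draw_cohort_params <- function(spec) {
  with_local_seed(spec$seed, {
    rows <- list()
    m <- 0L
    for (g in names(spec$groups)) {
      gr <- spec$groups[[g]]
      for (i in seq_len(gr$n)) {
        m <- m + 1L
        rows[[m]] <- data.frame(
          mouse = sprintf("m%02d", m), group = g,
          peak_circ_shortening = max(0.02,
            stats::rnorm(1, gr$peak_circ_shortening[1], gr$peak_circ_shortening[2])),
          twist_scale = stats::rnorm(1, gr$twist_scale[1], gr$twist_scale[2]),
          long_shortening = min(0.3, max(0,
            stats::rnorm(1, gr$long_shortening[1], gr$long_shortening[2]))),
          jit_basal = stats::rnorm(1, 0, spec$inter_test_slice_jitter_sd),
          jit_mid = stats::rnorm(1, 0, spec$inter_test_slice_jitter_sd),
          jit_apical = stats::rnorm(1, 0, spec$inter_test_slice_jitter_sd),
          seed_day1 = sample.int(.Machine$integer.max - 10L, 1),
          seed_day2 = sample.int(.Machine$integer.max - 10L, 1),
          seed_obs2 = sample.int(.Machine$integer.max - 10L, 1),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

# Build one animal's deformation model from its drawn parameters.
mouse_model <- function(spec, prow) {
  base_profile <- spec$twist_profile
  if (is.null(base_profile)) {
    base_profile <- twist_profile_points(
      positions = c(0.3, 0.5, 0.7) / (1 - prow$long_shortening),
      angles_deg = c(4.5, 0.5, -2.2))
  }
  sc <- prow$twist_scale
  deformation_model(
    peak_circ_shortening = prow$peak_circ_shortening,
    long_shortening = prow$long_shortening,
    twist_profile = function(z) sc * base_profile(z)
  )
}

# Render one animal under one condition.  "obs2_day1" reuses the day-1
# images (identical seed) with observer-perturbed contours.
simulate_mouse_condition <- function(spec, prow, condition) {
  model <- mouse_model(spec, prow)
  day2 <- condition == "obs1_day2"
  # with both inter-test degradations disabled, day 2 is an exact
  # re-acquisition of day 1
  repeat_exact <- spec$inter_test_noise_sd == 0 &&
    spec$inter_test_slice_jitter_sd == 0
  seed <- if (day2 && !repeat_exact) prow$seed_day2 else prow$seed_day1
  series <- list()
  ctr <- list()
  with_local_seed(seed, {
    for (id in spec$slices) {
      sl <- slice_descriptor(id)
      if (day2 && sl$orientation == "short_axis") {
        jit <- prow[[paste0("jit_", id)]]
        sl$position <- sl$position + jit / model$lv_length_ed
      }
      series[[id]] <- tryCatch(
        render_dense_series(model, spec$acquisition, sl),
        error = function(e) stop("mouse ", prow$mouse, ", condition ",
                                 condition, ", slice ", id, ": ",
                                 conditionMessage(e)))
      if (sl$orientation == "short_axis") {
        ctr[[id]] <- model_contours(model, sl)
      }
    }
  })
  if (condition == "obs2_day1" && spec$observer_contour_jitter_sd > 0) {
    for (i in seq_along(ctr)) {
      ctr[[i]] <- perturb_contours(ctr[[i]], spec$observer_contour_jitter_sd,
                                   rng_seed = prow$seed_obs2 + i)
    }
  }
  list(series = series, contours = ctr, model = model)
}

#' Simulate a full virtual cohort
#'
#' @param spec A [cohort_spec()].
#' @param conditions Conditions to simulate.
#' @return A `dense_cohort`: per-animal list of per-condition data
#'   (`series`, `contours`), the drawn parameters, and the ground-truth
#'   endpoint table.  Fully reproducible from `spec$seed`.
#' @export
simulate_cohort <- function(spec,
                            conditions = c("obs1_day1", "obs1_day2", "obs2_day1")) {
  stopifnot(inherits(spec, "cohort_spec"))
  prm <- draw_cohort_params(spec)
  mice <- list()
  truth <- list()
  for (i in seq_len(nrow(prm))) {
    prow <- prm[i, ]
    dat <- list()
    for (cond in conditions) {
      dat[[cond]] <- simulate_mouse_condition(spec, prow, cond)
    }
    mice[[prow$mouse]] <- dat
    tr <- ground_truth_endpoints(mouse_model(spec, prow), spec)
    tr$mouse <- prow$mouse
    tr$group <- prow$group
    truth[[i]] <- tr
  }
  structure(list(spec = spec, params = prm, mice = mice,
                 truth = do.call(rbind, truth)),
            class = "dense_cohort")
}

#' Ground-truth endpoints of a deformation model
#'
#' Exact model values of the principal endpoints: peak strains per transmural
#' layer (aggregated over the end-diastolic pixel grid exactly as the
#' analysis aggregates its material points), end-systolic twist per slice
#' (evaluated at the material position imaged at end systole), and peak
#' torsion.
#'
#' @param model A [deformation_model()].
#' @param spec A [cohort_spec()] (for the acquisition grid); defaults used if
#'   missing.
#' @return Data frame with `endpoint`, `value`.
#' @export
ground_truth_endpoints <- function(model, spec = NULL) {
  acq <- if (is.null(spec)) acquisition_spec() else spec$acquisition
  dx <- acq$pixel_spacing
  ax <- pixel_axes(acq$matrix_size, dx)
  px <- rep(ax, times = length(ax))
  py <- rep(ax, each = length(ax))
  R <- sqrt(px^2 + py^2)
  inside <- R >= model$endo_radius_ed & R <= model$epi_radius_ed
  R <- R[inside]
  t_es <- model_es_time(model)
  st <- model_strain_polar(model, R, t_es)
  depth <- (R - model$endo_radius_ed) /
    (model$epi_radius_ed - model$endo_radius_ed)
  layer <- as.character(cut(depth, c(-0.001, 1 / 3, 2 / 3, 1.001),
                            labels = c("endo", "mid", "epi")))
  rows <- list()
  add <- function(name, value) rows[[length(rows) + 1]] <<-
    data.frame(endpoint = name, value = value, stringsAsFactors = FALSE)
  for (dir in c("cc", "rr")) {
    v <- 100 * st[[paste0("E_", dir)]]
    for (lay in c("endo", "mid", "epi")) {
      add(paste0("peak_", dir, "_", lay), mean(v[layer == lay]))
    }
    add(paste0("peak_", dir, "_global"), mean(v))
  }
  add("peak_ll_global", 100 * st$E_ll)
  sl <- c(basal = 0.7, mid = 0.5, apical = 0.3)
  for (id in names(sl)) {
    add(paste0("es_twist_", id), model_true_twist(model, sl[[id]]))
  }
  tw_b <- model_true_twist(model, sl[["basal"]])
  tw_a <- model_true_twist(model, sl[["apical"]])
  add("peak_torsion", (tw_a - tw_b) / (model$lv_length_ed / 10))
  add("cure_total", 1)
  add("rure_total", 1)
  do.call(rbind, rows)
}
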