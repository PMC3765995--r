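#' Analytic left-ventricular deformation model
#'
#' Builds an incompressible contracting/twisting annulus model of the mouse
#' left ventricle.  In reference polar coordinates (R, Theta, Z) a material
#' point moves to
#' \deqn{r(R,t) = \sqrt{R^2 - R_{endo}^2 + r_{endo}(t)^2}}
#' \deqn{\theta(t) = \Theta + \mathrm{twist}(Z/L)\,a(t)}
#' \deqn{z(t) = Z\,(1 - \lambda_{ls}\,a(t))}
#' where \eqn{r_{endo}(t) = R_{endo}(1 - s\,a(t))} with `s` the peak
#' endocardial circumferential shortening fraction and \eqn{a(t)} the temporal
#' activation (0 at end diastole, 1 at end systole).  The radial map conserves
#' in-plane area (2D incompressibility), which reproduces the characteristic
#' endocardium-to-epicardium gradient in circumferential strain.
#'
#' The model exposes exact displacement and exact Green-Lagrange strain at any
#' point and time, serving as ground truth for the full analysis pipeline.
#'
#' @param endo_radius_ed Endocardial radius at end diastole (mm).
#' @param epi_radius_ed Epicardial radius at end diastole (mm).
#' @param lv_length_ed Long-axis epicardial length at end diastole (mm).
#' @param peak_circ_shortening Peak endocardial circumferential shortening
#'   fraction (dimensionless; 0.18 gives peak endocardial Ecc of about -16%).
#' @param long_shortening Peak longitudinal shortening fraction
#'   (0.12 gives peak Ell of about -11%).
#' @param twist_profile Function of normalized long-axis position
#'   (0 = apex, 1 = base) returning the peak twist angle in degrees; must be
#'   non-increasing (positive toward the apex, negative toward the base).
#'   Defaults to a piecewise-linear profile anchored so that the three standard
#'   short-axis slices read +4.5 (apical), +0.5 (mid) and -2.2 (basal) degrees
#'   at end systole.
#' @param temporal_activation Function of time (ms) returning activation in
#'   `[0, 1]`; defaults to a smooth squared-sine rise reaching 1 at
#'   `systole_fraction * cycle_length` and returning to 0 at end of cycle.
#' @param cycle_length Cardiac cycle length (ms).
#' @param systole_fraction Fraction of the cycle at which activation peaks.
#' @return An object of class `deformation_model`.
#' @examples
#' m <- deformation_model()
#' model_strain_polar(m, R = 1.2, t = model_es_time(m))$E_cc
#' @export
deformation_model <- function(endo_radius_ed = 1.2,
                              epi_radius_ed = 2.2,
                              lv_length_ed = 8.5,
                              peak_circ_shortening = 0.18,
                              long_shortening = 0.12,
                              twist_profile = NULL,
                              temporal_activation = NULL,
                              cycle_length = 110,
                              systole_fraction = 0.4) {
  if (!(epi_radius_ed > endo_radius_ed && endo_radius_ed > 0)) {
    stop("require epi_radius_ed > endo_radius_ed > 0")
  }
  if (peak_circ_shortening >= 1) {
    stop("cavity collapse: peak_circ_shortening must be < 1 ",
         "(endocardial radius would reach zero)")
  }
  if (long_shortening >= 1 || long_shortening < 0) {
    stop("long_shortening must lie in [0, 1)")
  }
  if (is.null(temporal_activation)) {
    temporal_activation <- make_activation(cycle_length, systole_fraction)
  }
  a0 <- temporal_activation(0)
  if (abs(a0) > 1e-9) stop("temporal_activation(0) must be 0")
  grid <- seq(0, cycle_length, length.out = 512)
  amax <- max(vapply(grid, temporal_activation, numeric(1)))
  if (abs(amax - 1) > 1e-3) {
    stop("temporal_activation must attain 1 within the cycle")
  }
  if (is.null(twist_profile)) {
    twist_profile <- twist_profile_points(
      positions = c(0.3, 0.5, 0.7) / (1 - long_shortening),
      angles_deg = c(4.5, 0.5, -2.2)
    )
  }
  zg <- seq(0, 1, length.out = 64)
  tw <- vapply(zg, twist_profile, numeric(1))
  if (any(diff(tw) > 1e-9)) {
    stop("twist_profile must be non-increasing from apex (position 0) to base")
  }
  structure(list(
    endo_radius_ed = endo_radius_ed,
    epi_radius_ed = epi_radius_ed,
    lv_length_ed = lv_length_ed,
    peak_circ_shortening = peak_circ_shortening,
    long_shortening = long_shortening,
    twist_profile = twist_profile,
    temporal_activation = temporal_activation,
    cycle_length = cycle_length,
    systole_fraction = systole_fraction
  ), class = "deformation_model")
}

#' @export
print.deformation_model <- function(x, ...) {
  cat("Left-ventricular deformation model\n")
  cat(sprintf("  endo/epi radius (ED): %.2f / %.2f mm, length %.2f mm\n",
              x$endo_radius_ed, x$epi_radius_ed, x$lv_length_ed))
  cat(sprintf("  peak circ. shortening %.3f, long. shortening %.3f\n",
              x$peak_circ_shortening, x$long_shortening))
  cat(sprintf("  cycle %.1f ms, end systole at %.1f ms\n",
              x$cycle_length, model_es_time(x)))
  invisible(x)
}

# Smooth activation: squared-sine rise over systole, squared-sine return.
make_activation <- function(cycle_length, systole_fraction = 0.4) {
  t_es <- systole_fraction * cycle_length
  force(cycle_length)
  function(t) {
    t <- t %% cycle_length
    ifelse(t <= t_es,
           sin(pi * t / (2 * t_es))^2,
           sin(pi * (cycle_length - t) / (2 * (cycle_length - t_es)))^2)
  }
}

#' Piecewise-linear twist profile through anchor points
#'
#' @param positions Normalized long-axis positions (0 = apex, 1 = base).
#' @param angles_deg Peak twist angles (degrees) at those positions; must be
#'   non-increasing toward the base.
#' @return A function of normalized position, linearly interpolated between
#'   anchors and constant beyond them.
#' @export
twist_profile_points <- function(positions, angles_deg) {
  ord <- order(positions)
  positions <- positions[ord]
  angles_deg <- angles_deg[ord]
  f <- stats::approxfun(positions, angles_deg, rule = 2)
  f
}

#' Linear twist profile with a given gradient and zero crossing
#'
#' Convenience for a twist gradient that is exactly linear along the long
#' axis, so that torsion is independent of slice position.
#'
#' @param gradient_deg_per_unit Twist change per unit normalized long-axis
#'   position (degrees; negative means twist decreases toward the base).
#' @param zero_position Normalized position at which twist crosses zero.
#' @return A function of normalized position.
#' @export
twist_profile_linear <- function(gradient_deg_per_unit, zero_position = 0.5) {
  function(z) gradient_deg_per_unit * (z - zero_position)
}

#' Time of end systole of a deformation model
#'
#' @param model A [deformation_model()].
#' @return Time (ms) at which the temporal activation peaks.
#' @export
model_es_time <- function(model) {
  model$systole_fraction * model$cycle_length
}

# Endocardial radius at activation level a.
endo_radius_at <- function(model, a) {
  r <- model$endo_radius_ed * (1 - model$peak_circ_shortening * a)
  if (any(r <= 0)) stop("cavity collapse: endocardial radius reached zero")
  r
}

# Deformed radius of material at reference radius R, activation a.
deformed_radius <- function(model, R, a) {
  re <- endo_radius_at(model, a)
  sqrt(R^2 - model$endo_radius_ed^2 + re^2)
}

#' Exact material position under the deformation model
#'
#' @param model A [deformation_model()].
#' @param R,Theta,Z Reference polar coordinates (mm, radians, mm from apex).
#' @param t Time (ms).
#' @return A list with deformed coordinates `r`, `theta`, `z` and Cartesian
#'   `x`, `y`.
#' @export
model_material_position <- function(model, R, Theta, Z, t) {
  a <- model$temporal_activation(t)
  r <- deformed_radius(model, R, a)
  tw <- model$twist_profile(Z / model$lv_length_ed) * a * pi / 180
  theta <- Theta + tw
  z <- Z * (1 - model$long_shortening * a)
  list(r = r, theta = theta, z = z, x = r * cos(theta), y = r * sin(theta))
}

#' Exact Eulerian in-plane displacement for a short-axis slice
#'
#' For pixels at laboratory position (x, y) in the fixed imaging plane at
#' height `z_lab`, returns the in-plane displacement of the tissue currently
#' occupying each pixel (current minus reference position), together with the
#' myocardial membership mask.  This is exactly what DENSE phase encodes.
#'
#' @param model A [deformation_model()].
#' @param x,y Laboratory coordinates (mm), vectors of equal length.
#' @param z_lab Laboratory slice height above the apex (mm).
#' @param t Time (ms).
#' @return List with `ux`, `uy` (NA outside the myocardium) and logical
#'   `inside`.
#' @export
model_eulerian_displacement <- function(model, x, y, z_lab, t) {
  a <- model$temporal_activation(t)
  re <- endo_radius_at(model, a)
  rep_ <- deformed_radius(model, model$epi_radius_ed, a)
  r <- sqrt(x^2 + y^2)
  lz <- 1 - model$long_shortening * a
  Z <- z_lab / lz
  inside <- r >= re & r <= rep_ & Z >= 0 & Z <= model$lv_length_ed
  ux <- rep(NA_real_, length(x)); uy <- ux
  if (any(inside)) {
    ri <- r[inside]
    R <- sqrt(ri^2 - re^2 + model$endo_radius_ed^2)
    tw <- model$twist_profile(Z / model$lv_length_ed) * a * pi / 180
    Theta <- atan2(y[inside], x[inside]) - tw
    ux[inside] <- x[inside] - R * cos(Theta)
    uy[inside] <- y[inside] - R * sin(Theta)
  }
  list(ux = ux, uy = uy, inside = inside)
}

# Long-axis analogue: imaging plane contains the long axis; in-plane
# coordinates are (x across the ventricle, z along it, measured from apex).
model_eulerian_displacement_la <- function(model, x, z, t) {
  a <- model$temporal_activation(t)
  re <- endo_radius_at(model, a)
  rep_ <- deformed_radius(model, model$epi_radius_ed, a)
  lz <- 1 - model$long_shortening * a
  Z <- z / lz
  r <- abs(x)
  inside <- r >= re & r <= rep_ & Z >= 0 & Z <= model$lv_length_ed
  ux <- rep(NA_real_, length(x)); uz <- ux
  if (any(inside)) {
    ri <- r[inside]
    R <- sqrt(ri^2 - re^2 + model$endo_radius_ed^2)
    tw <- model$twist_profile(Z[inside] / model$lv_length_ed) * a * pi / 180
    theta0 <- ifelse(x[inside] >= 0, 0, pi)
    Theta <- theta0 - tw
    ux[inside] <- x[inside] - R * cos(Theta)
    uz[inside] <- z[inside] - Z[inside]
  }
  list(ux = ux, uz = uz, inside = inside)
}

#' Exact Green-Lagrange strain of the annulus model
#'
#' In the reference polar basis the in-plane deformation gradient is diagonal
#' (radial stretch R/r is the reciprocal of the... see vignette), giving
#' \eqn{E_{rr} = ((dr/dR)^2 - 1)/2}, \eqn{E_{cc} = ((r/R)^2 - 1)/2}, and
#' \eqn{E_{ll} = ((1 - \lambda_{ls} a)^2 - 1)/2}.
#'
#' @param model A [deformation_model()].
#' @param R Reference radius (mm), vectorized.
#' @param t Time (ms).
#' @return List with `E_rr`, `E_cc`, `E_ll` (dimensionless).
#' @export
model_strain_polar <- function(model, R, t) {
  a <- model$temporal_activation(t)
  r <- deformed_radius(model, R, a)
  lam_c <- r / R
  lam_r <- R / r   # d r / d R = R / r for the area-preserving map
  lam_l <- 1 - model$long_shortening * a
  list(E_rr = (lam_r^2 - 1) / 2,
       E_cc = (lam_c^2 - 1) / 2,
       E_ll = (lam_l^2 - 1) / 2)
}

#' Ground-truth twist read by a fixed laboratory slice
#'
#' Slices image a fixed laboratory plane while the ventricle shortens through
#' it; the twist a slice reads at time `t` is that of the material shell
#' currently intersecting the plane.  The reported ground truth is evaluated at
#' the material position imaged at end systole.
#'
#' @param model A [deformation_model()].
#' @param slice_position Normalized end-diastolic long-axis slice position.
#' @param t Time (ms); defaults to end systole.
#' @return Twist in degrees.
#' @export
model_true_twist <- function(model, slice_position, t = model_es_time(model)) {
  a <- model$temporal_activation(t)
  z_lab <- slice_position * model$lv_length_ed
  Z <- z_lab / (1 - model$long_shortening * a)
  model$twist_profile(Z / model$lv_length_ed) * a
}
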