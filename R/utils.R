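#' Wrap phase to the interval (-pi, pi]
#'
#' @param x Numeric vector or array of phase values in radians.
#' @return `x` reduced modulo 2*pi into (-pi, pi].
#' @export
wrap_phase <- function(x) {
  x - 2 * pi * ceiling(x / (2 * pi) - 0.5)
}

# Preserve the caller's RNG stream when a local seed is requested.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = .GlobalEnv), add = TRUE)
  }
  set.seed(seed)
  code
}

# Physical coordinates (mm) of pixel centres; origin at the image centre.
pixel_axes <- function(n, spacing) {
  (seq_len(n) - (n + 1) / 2) * spacing
}

# Bounding box (row/col ranges, with margin) of a logical mask.
mask_bbox <- function(mask, margin = 3L) {
  idx <- which(mask, arr.ind = TRUE)
  c(max(1L, min(idx[, 1]) - margin), min(nrow(mask), max(idx[, 1]) + margin),
    max(1L, min(idx[, 2]) - margin), min(ncol(mask), max(idx[, 2]) + margin))
}

# Binary dilation of a logical matrix by `k` 4-connected steps.
dilate_mask <- function(mask, k = 1) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- mask
  for (s in seq_len(k)) {
    shifted <- out
    shifted[-1, ] <- shifted[-1, ] | out[-nr, ]
    shifted[-nr, ] <- shifted[-nr, ] | out[-1, ]
    shifted[, -1] <- shifted[, -1] | out[, -nc]
    shifted[, -nc] <- shifted[, -nc] | out[, -1]
    out <- shifted
  }
  out
}

# Keep only the largest 4-connected component of a mask.
largest_component <- function(mask) {
  lab <- label_components_cpp(mask)
  if (max(lab) <= 1L) return(mask)
  tab <- tabulate(lab[lab > 0L])
  lab == which.max(tab)
}

# Extend a masked field into a collar outside its support so that bilinear
# sampling stays defined just beyond the mask: each collar pixel takes the
# value at its location of a plane fit over the masked pixels in its 5x5
# window (gradient-faithful, exact for affine fields).  Pixels sharing a
# window occupancy pattern share one projection vector.
fill_collar <- function(img, passes = 3L) {
  mask <- !is.na(img)
  if (!any(mask) || all(mask)) return(img)
  collar <- dilate_mask(mask, passes) & !mask
  nr <- nrow(img); nc <- ncol(img)
  offs <- expand.grid(di = -2:2, dj = -2:2)
  n_off <- nrow(offs)
  ev <- which(collar)
  ei <- (ev - 1) %% nr + 1
  ej <- (ev - 1) %/% nr + 1
  nbr_val <- matrix(0, length(ev), n_off)
  nbr_ok <- matrix(FALSE, length(ev), n_off)
  for (k in seq_len(n_off)) {
    ii <- ei + offs$di[k]; jj <- ej + offs$dj[k]
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    idx <- (jj[ok] - 1) * nr + ii[ok]
    good <- mask[idx]
    sel <- which(ok)[good]
    nbr_ok[sel, k] <- TRUE
    nbr_val[sel, k] <- img[idx[good]]
  }
  sig <- as.vector(nbr_ok %*% 2^(seq_len(n_off) %% 31))
  fill <- rep(NA_real_, length(ev))
  for (s in unique(sig)) {
    rows <- which(sig == s)
    patt <- nbr_ok[rows[1], ]
    if (sum(patt) < 3) next
    B <- cbind(1, offs$di[patt], offs$dj[patt])
    P <- tryCatch(solve(crossprod(B), t(B))[1, ], error = function(e) NULL)
    if (is.null(P)) {
      # collinear support: fall back to the window mean
      fill[rows] <- rowSums(nbr_val[rows, patt, drop = FALSE]) / sum(patt)
    } else {
      fill[rows] <- as.vector(nbr_val[rows, patt, drop = FALSE] %*% P)
    }
  }
  out <- img
  keep <- !is.na(fill)
  out[ev[keep]] <- fill[keep]
  # any remaining unfilled collar (degenerate windows): nearest-mean passes
  remaining <- collar & is.na(out)
  for (p in seq_len(passes)) {
    if (!any(remaining)) break
    acc <- matrix(0, nr, nc); cnt <- matrix(0L, nr, nc)
    for (sh in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      v <- shift_matrix(out, sh[1], sh[2])
      ok <- !is.na(v)
      acc[ok] <- acc[ok] + v[ok]
      cnt <- cnt + ok
    }
    f <- remaining & cnt > 0L
    out[f] <- acc[f] / cnt[f]
    remaining <- collar & is.na(out)
  }
  out
}

# Shift a matrix by (di, dj), padding with NA.
shift_matrix <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  if (abs(di) >= nr || abs(dj) >= nc) return(out)
  si <- max(1, 1 + di):min(nr, nr + di)
  sj <- max(1, 1 + dj):min(nc, nc + dj)
  out[si, sj] <- m[si - di, sj - dj, drop = FALSE]
  out
}

# Bilinear interpolation of a matrix at continuous (1-based) index positions.
# Returns NA where any participating node is NA or out of range.
bilinear <- function(img, xi, yi) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(xi); y0 <- floor(yi)
  fx <- xi - x0;   fy <- yi - y0
  ok <- x0 >= 1 & x0 <= nr - 1 & y0 >= 1 & y0 <= nc - 1
  out <- rep(NA_real_, length(xi))
  if (!any(ok)) return(out)
  i0 <- x0[ok]; j0 <- y0[ok]; gx <- fx[ok]; gy <- fy[ok]
  v00 <- img[cbind(i0, j0)]
  v10 <- img[cbind(i0 + 1, j0)]
  v01 <- img[cbind(i0, j0 + 1)]
  v11 <- img[cbind(i0 + 1, j0 + 1)]
  out[ok] <- (1 - gx) * (1 - gy) * v00 + gx * (1 - gy) * v10 +
    (1 - gx) * gy * v01 + gx * gy * v11
  out
}

# Savitzky-Golay smoothing of a curve: each value is replaced by the
# intercept of a local quadratic fit over up to `half` neighbours each side.
# Exact for locally quadratic curves (so smooth peaks are preserved).
sg_smooth_curve <- function(v, half = 3L) {
  n <- length(v)
  out <- v
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    if (hi - lo + 1L <= 3L) next
    x <- (lo:hi) - i
    out[i] <- stats::lm.fit(cbind(1, x, x^2), v[lo:hi])$coefficients[1]
  }
  out
}

# Robust estimate of the per-pixel displacement noise SD (mm): the discrete
# Laplacian of a smooth deformation field is small at an early cine frame,
# so its masked MAD is dominated by pixel noise
# (Var(Laplacian) = 20 sigma^2 for i.i.d. noise).
estimate_field_noise <- function(disp) {
  f <- min(2L, dim(disp$u_x)[3])
  ests <- c()
  for (comp in c("u_x", "u_y")) {
    u <- disp[[comp]][, , f]
    u[!disp$mask[, , f]] <- NA_real_
    lap <- 4 * u - shift_matrix(u, 1, 0) - shift_matrix(u, -1, 0) -
      shift_matrix(u, 0, 1) - shift_matrix(u, 0, -1)
    v <- lap[!is.na(lap)]
    if (length(v) >= 20) ests <- c(ests, stats::mad(v) / sqrt(20))
  }
  if (length(ests) == 0) return(0)
  mean(ests)
}

# Crossing-number point-in-polygon test, vectorised over query points.
# poly: n x 2 matrix of vertices (closed implicitly).
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- poly[c(2:n, 1), 1]; y2 <- poly[c(2:n, 1), 2]
  inside <- rep(FALSE, length(px))
  for (e in seq_len(n)) {
    crosses <- (y1[e] > py) != (y2[e] > py)
    if (any(crosses)) {
      xint <- x1[e] + (py[crosses] - y1[e]) / (y2[e] - y1[e]) * (x2[e] - x1[e])
      flip <- px[crosses] < xint
      inside[crosses][flip] <- !inside[crosses][flip]
    }
  }
  inside
}

# Shoelace centroid of a simple closed polygon given as n x 2 matrix.
polygon_centroid <- function(poly) {
  n <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- poly[c(2:n, 1), 1]; yn <- poly[c(2:n, 1), 2]
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

# Circular mean of angles in degrees.
circular_mean_deg <- function(deg) {
  rad <- deg * pi / 180
  atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
}

# Centered finite-difference rate of a curve; one-sided at the ends.
finite_diff_rate <- function(values, times) {
  n <- length(values)
  stopifnot(length(times) == n, n >= 2)
  rate <- numeric(n)
  rate[1] <- (values[2] - values[1]) / (times[2] - times[1])
  rate[n] <- (values[n] - values[n - 1]) / (times[n] - times[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    rate[i] <- (values[i + 1] - values[i - 1]) / (times[i + 1] - times[i - 1])
  }
  rate
}
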