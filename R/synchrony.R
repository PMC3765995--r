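#' Circumferential/radial uniformity ratio estimate (CURE/RURE)
#'
#' Spatial-Fourier synchrony index.  At each frame the strain field is
#' averaged in angular sectors about the centroid; a least-squares fit of
#' `s_k = a0 + a1 cos(theta_k) + b1 sin(theta_k)` gives the zeroth- and
#' first-harmonic powers `S0 = a0^2` and `S1 = a1^2 + b1^2`.  The index is
#' `sum(S0) / sum(S0 + S1)` over the frame window (powers summed across
#' slices when several are supplied): 1 for perfectly uniform (synchronous)
#' contraction, 0 for a pure first-harmonic (dyssynchronous) pattern.
#'
#' @param strain `[points x frames]` matrix of directional strain
#'   (circumferential for CURE, radial for RURE), or a list of such matrices
#'   (one per short-axis slice).
#' @param angles Per-point angular position about the slice centroid
#'   (radians); a list when `strain` is a list.
#' @param n_sectors Number of angular sectors (>= 4).
#' @param window Frame indices to include; all frames if `NULL`.
#' @param sqrt_variant If `TRUE`, return the square root of the power ratio
#'   (an alternative form found in the literature).
#' @return Index in `[0, 1]`.
#' @export
uniformity_ratio <- function(strain, angles, n_sectors = 24, window = NULL,
                             sqrt_variant = FALSE) {
  if (!is.list(strain)) {
    strain <- list(strain)
    angles <- list(angles)
  }
  stopifnot(length(strain) == length(angles), n_sectors >= 4)
  nf <- ncol(strain[[1]])
  if (is.null(window)) window <- seq_len(nf)
  if (length(window) == 0) stop("empty frame window")
  S0_tot <- 0; S1_tot <- 0
  edges <- seq(-pi, pi, length.out = n_sectors + 1)
  for (s in seq_along(strain)) {
    v <- strain[[s]]
    th <- angles[[s]]
    ok <- !is.na(v[, 1]) & !is.na(th)
    v <- v[ok, , drop = FALSE]
    th <- th[ok]
    sect <- cut(th, breaks = edges, include.lowest = TRUE, labels = FALSE)
    centers <- (edges[-1] + edges[-(n_sectors + 1)]) / 2
    X <- cbind(1, cos(centers), sin(centers))
    for (f in window) {
      sk <- vapply(seq_len(n_sectors), function(k) {
        pts <- sect == k
        if (!any(pts)) return(NA_real_)
        mean(v[pts, f])
      }, numeric(1))
      if (anyNA(sk)) {
        stop("empty angular sector ", which(is.na(sk))[1], " at frame ", f)
      }
      coef <- qr.solve(X, sk)
      S0_tot <- S0_tot + coef[1]^2
      S1_tot <- S1_tot + coef[2]^2 + coef[3]^2
    }
  }
  if (S0_tot + S1_tot == 0) {
    message("all-zero strain in window: uniformity ratio defined as 1")
    return(1)
  }
  idx <- S0_tot / (S0_tot + S1_tot)
  idx <- min(max(idx, 0), 1)
  if (sqrt_variant) sqrt(idx) else idx
}

#' Frame windows for synchrony indices
#'
#' @param es_frame End-systolic frame (1-based), strictly inside the cycle.
#' @param n_frames Total number of frames.
#' @return List of integer frame vectors `total`, `systolic` (frames up to
#'   and including end systole) and `diastolic` (frames after it); the two
#'   sub-windows partition the total window.
#' @export
synchrony_windows <- function(es_frame, n_frames) {
  if (!(es_frame > 1 && es_frame < n_frames)) {
    stop("degenerate end-systolic frame: must satisfy 1 < es_frame < n_frames")
  }
  list(total = seq_len(n_frames),
       systolic = seq_len(es_frame),
       diastolic = seq(es_frame + 1, n_frames))
}
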