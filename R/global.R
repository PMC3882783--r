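# Twist, torsion and the CURE/RURE uniformity (synchrony) indices.

#' Slice twist angle from tracked material points
#'
#' Per frame, the mean over valid points of the signed angle between the
#' reference position vector (X - centroid) and the current position vector
#' (x(t) - centroid). Counter-clockwise rotation is positive; frame 1 is
#' zero by construction.
#'
#' @param points A \code{\link{track_points}} result.
#' @param centroid Length-2 rotation centre, mm (end-diastolic epicardial
#'   centroid).
#' @return Numeric vector of twist angles per frame, degrees.
#' @export
twist_angle <- function(points, centroid) {
  stopifnot(inherits(points, "material_points"))
  nfr <- dim(points$traj)[3]
  out <- numeric(nfr)
  for (k in seq_len(nfr)) {
    ok <- points$valid[, k]
    if (sum(ok) < 10L)
      stop(sprintf("too few valid points (%d) for twist at frame %d",
                   sum(ok), k))
    v0 <- points$reference[ok, , drop = FALSE] -
      matrix(centroid, sum(ok), 2, byrow = TRUE)
    v1 <- points$traj[ok, , k, drop = FALSE][, , 1] -
      matrix(centroid, sum(ok), 2, byrow = TRUE)
    ang <- atan2(v0[, 1] * v1[, 2] - v0[, 2] * v1[, 1],
                 rowSums(v0 * v1))
    out[k] <- rad2deg(mean(ang))
  }
  out
}

#' Torsion from basal and apical twist curves
#'
#' Torsion is the basal-to-apical twist difference normalised by the
#' end-diastolic epicardial long-axis length (the average of the two- and
#' four-chamber measurements), in degrees/cm.  Peak torsion is the signed
#' value of maximal magnitude.
#'
#' @param twist_base,twist_apex Twist curves, degrees per frame.
#' @param length_cm Normalisation length, cm.
#' @return Object of class \code{torsion_result}: \code{torsion_curve}
#'   (degrees/cm), \code{peak_torsion} (degrees/cm),
#'   \code{peak_torsion_deg_per_mm}, plus the inputs.
#' @export
#' @examples
#' torsion(rep(0, 3), c(0, 4, 8.8), 1.0)$peak_torsion   # 8.8 deg/cm
torsion <- function(twist_base, twist_apex, length_cm) {
  if (length(twist_base) != length(twist_apex))
    stop("twist curves must have equal length")
  if (!is.numeric(length_cm) || length_cm <= 0)
    stop("normalisation length must be positive")
  curve <- (twist_apex - twist_base) / length_cm
  peak <- curve[which.max(abs(curve))]
  structure(list(twist_base = twist_base, twist_apex = twist_apex,
                 normalization_length = length_cm, torsion_curve = curve,
                 peak_torsion = peak,
                 peak_torsion_deg_per_mm = peak / 10),
            class = "torsion_result")
}

#' @export
print.torsion_result <- function(x, ...) {
  cat(sprintf("peak torsion %.2f deg/cm (%.3f deg/mm), L = %.2f cm\n",
              x$peak_torsion, x$peak_torsion_deg_per_mm,
              x$normalization_length))
  invisible(x)
}

#' Uniformity ratio estimate (CURE/RURE) of sector strain curves
#'
#' Fourier-harmonic synchrony index of the spatial strain profile around the
#' ventricle.  Per frame, the discrete Fourier coefficients c_k of the
#' N-sector strain profile give the zeroth-harmonic power P0 = |c0|^2 and
#' first-harmonic power P1 = |c1|^2 + |c_{N-1}|^2; the index is
#' sum_t P0 / sum_t (P0 + P1), in (0, 1], with 1 meaning perfectly uniform
#' (synchronous) contraction.  Applied to circumferential sector strains the
#' index is CURE; to radial sector strains, RURE.
#'
#' @param sector_curves N x T matrix: strain versus frame for N equal
#'   angular sectors (N >= 8, T >= 2).
#' @return Object of class \code{synchrony_result}: \code{index}, and
#'   per-frame \code{P0}, \code{P1} diagnostics.
#' @export
uniformity_index <- function(sector_curves) {
  sector_curves <- as.matrix(sector_curves)
  N <- nrow(sector_curves); Tn <- ncol(sector_curves)
  if (N < 8L) stop("need at least 8 sectors")
  if (Tn < 2L) stop("need at least 2 frames")
  P0 <- numeric(Tn); P1 <- numeric(Tn)
  for (t in seq_len(Tn)) {
    ck <- stats::fft(sector_curves[, t]) / N
    P0[t] <- Mod(ck[1])^2
    P1[t] <- Mod(ck[2])^2 + Mod(ck[N])^2
  }
  tot <- sum(P0) + sum(P1)
  if (tot == 0)
    stop("undefined uniformity index: zero strain profile at every frame")
  structure(list(index = sum(P0) / tot, P0 = P0, P1 = P1),
            class = "synchrony_result")
}

#' @export
print.synchrony_result <- function(x, ...) {
  cat(sprintf("uniformity index %.4f over %d frames\n", x$index, length(x$P0)))
  invisible(x)
}

#' Sector strain curves from per-point strain samples
#'
#' Bins the per-point samples of one short-axis slice into N equal angular
#' sectors and returns the sector-mean strain versus frame, the input the
#' uniformity indices are computed from.
#'
#' @param samples A \code{\link{strain_samples}} data.frame.
#' @param direction \code{"circumferential"} or \code{"radial"}.
#' @param n_sectors Number of sectors (default 24).
#' @param origin_angle_deg Angular origin, degrees; sector 1 is centred on
#'   this angle (centring keeps the cardinal and diagonal image directions
#'   away from bin edges).
#' @return \code{n_sectors x nframes} matrix (NA where a sector is empty).
#' @export
sector_curves <- function(samples, direction = c("circumferential", "radial"),
                          n_sectors = 24L, origin_angle_deg = -90) {
  direction <- match.arg(direction)
  col <- if (direction == "circumferential") "ecc" else "err"
  half <- pi / n_sectors
  rel <- ((samples$theta - deg2rad(origin_angle_deg) + half) %% (2 * pi)) /
    (2 * pi)
  sec <- pmin(floor(rel * n_sectors), n_sectors - 1L) + 1L
  frames <- sort(unique(samples$frame))
  out <- matrix(NA_real_, n_sectors, length(frames))
  for (ki in seq_along(frames)) {
    sel <- samples$frame == frames[ki] & !is.na(samples[[col]])
    m <- tapply(samples[[col]][sel], factor(sec[sel], levels = seq_len(n_sectors)),
                mean)
    out[, ki] <- as.numeric(m)
  }
  out
}
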