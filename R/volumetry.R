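# Volumetrics: smooth surface reconstruction from the three short-axis
# contours plus apex/base extent, and derived EDV/ESV/EF/mass.

# Lagrange interpolating polynomial through (zs, ys), evaluated at zq.
#' @keywords internal
lagrange_eval <- function(zs, ys, zq) {
  out <- numeric(length(zq))
  for (j in seq_along(zs)) {
    lj <- rep(1, length(zq))
    for (m in seq_along(zs)) {
      if (m == j) next
      lj <- lj * (zq - zs[m]) / (zs[j] - zs[m])
    }
    out <- out + ys[j] * lj
  }
  out
}

#' Reconstruct an LV surface from short-axis contours
#'
#' Surface-of-revolution-like reconstruction: for each of \code{n_rays}
#' angular rays from the long-axis centre, the squared radius profile is
#' interpolated polynomially in z through the three slice radii, pinned to
#' zero at the apex (when \code{apex_taper} is TRUE) and capped at the base
#' plane; the enclosed volume integrates the profile over z.  The squared-
#' radius parameterisation makes the reconstruction exact for ellipsoids of
#' revolution.
#'
#' @param contours List of three contour polygons (n x 2 matrices, mm),
#'   ordered apical, mid, basal.
#' @param slice_z Heights of the three slices above the apex, mm; must be
#'   strictly increasing in the apical-to-basal order given.
#' @param apex_z,base_z Apex and base heights, mm (from the long-axis
#'   views).
#' @param n_rays Number of angular rays.
#' @param apex_taper Pin the profile to zero radius at the apex.  With
#'   \code{FALSE} the polynomial uses the slice radii only (a cylinder when
#'   they are equal).
#' @return Object of class \code{lv_surface}: \code{volume} (uL = mm^3),
#'   per-ray slice \code{radii} (n_rays x 3), \code{slice_z}, \code{apex_z},
#'   \code{base_z}.
#' @export
reconstruct_surface <- function(contours, slice_z, apex_z, base_z,
                                n_rays = 72L, apex_taper = TRUE) {
  if (length(contours) != 3L || length(slice_z) != 3L)
    stop("need exactly three short-axis contours with slice heights")
  if (any(diff(slice_z) <= 0))
    stop("geometry error: slices out of order along the long axis")
  if (!(apex_z < slice_z[1] && base_z > slice_z[3]))
    stop("geometry error: apex/base extent does not bracket the slices")
  centers <- lapply(contours, polygon_centroid)
  axis_center <- colMeans(do.call(rbind, centers))
  th <- (seq_len(n_rays) - 0.5) * 2 * pi / n_rays
  radii <- sapply(contours, function(p) polygon_radius_at(p, axis_center, th))
  zq <- seq(apex_z, base_z, length.out = 201L)
  dz <- zq[2] - zq[1]
  vol <- 0
  for (k in seq_len(n_rays)) {
    if (apex_taper) {
      zs <- c(apex_z, slice_z); ys <- c(0, radii[k, ]^2)
    } else {
      zs <- slice_z; ys <- radii[k, ]^2
    }
    r2 <- pmax(lagrange_eval(zs, ys, zq), 0)
    vol <- vol + (pi / n_rays) * sum((r2[-1] + r2[-length(r2)]) / 2) * dz
  }
  structure(list(volume = vol, radii = radii, slice_z = slice_z,
                 apex_z = apex_z, base_z = base_z, axis_center = axis_center),
            class = "lv_surface")
}

#' Volumetric indices from reconstructed surfaces
#'
#' @param endo_ed,endo_es,epi_ed \code{lv_surface} objects for the
#'   endocardium at end-diastole and end-systole and the epicardium at
#'   end-diastole.
#' @param density Myocardial density, mg/uL (default 1.05, the standard CMR
#'   convention).
#' @return Object of class \code{volumetry_result} with \code{edv},
#'   \code{esv} (uL), \code{ef} (\%), \code{mass} (mg), \code{mass_to_edv}
#'   (mg/uL).
#' @export
#' @examples
#' # EF from printed group means: (61 - 25) / 61 = 59%
compute_volumetry <- function(endo_ed, endo_es, epi_ed, density = 1.05) {
  for (s in list(endo_ed, endo_es, epi_ed))
    stopifnot(inherits(s, "lv_surface"))
  if (any(epi_ed$radii < endo_ed$radii))
    stop("geometry error: endocardial surface crosses the epicardial surface")
  edv <- endo_ed$volume
  esv <- endo_es$volume
  if (esv >= edv)
    warning("end-systolic volume >= end-diastolic volume")
  mass <- density * (epi_ed$volume - endo_ed$volume)
  structure(list(edv = edv, esv = esv, ef = 100 * (edv - esv) / edv,
                 mass = mass, mass_to_edv = mass / edv),
            class = "volumetry_result")
}

#' @export
print.volumetry_result <- function(x, ...) {
  cat(sprintf("EDV %.1f uL, ESV %.1f uL, EF %.1f%%, mass %.1f mg (%.2f mg/uL)\n",
              x$edv, x$esv, x$ef, x$mass, x$mass_to_edv))
  invisible(x)
}
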