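# Tissue tracking and Lagrangian strain estimation.

#' Track material points through the cardiac cycle
#'
#' One material point is seeded per end-diastolic myocardial pixel centre.
#' For each frame the point's position x(t) solves x - u(x, t) = X (with X
#' the seed), found by local polynomial inverse interpolation of the
#' scattered Eulerian displacement samples; the solution is accepted when the
#' Lagrangian residual ||x - u(x, t) - X|| is below a tenth of the pixel
#' spacing. Points failing the residual or coverage test are flagged invalid
#' and stay invalid in later frames.
#'
#' @param field A \code{\link{compute_displacement_field}} result.
#' @param ed_mask Logical matrix marking end-diastolic myocardial pixels
#'   (defaults to the field's frame-1 mask).
#' @param residual_tol Acceptance threshold as a fraction of pixel spacing.
#' @param max_gap Maximum distance (pixels) from a seed's reference position
#'   to the nearest displacement sample.
#' @return Object of class \code{material_points}: \code{reference} (N x 2,
#'   mm), \code{traj} (N x 2 x nframes, mm), \code{valid} (N x nframes
#'   logical).
#' @export
track_points <- function(field, ed_mask = NULL, residual_tol = 0.1,
                         max_gap = 2.5) {
  stopifnot(inherits(field, "displacement_field"))
  if (is.null(ed_mask)) ed_mask <- field$mask[[1]]
  idx <- which(ed_mask)
  if (!length(idx)) stop("empty end-diastolic mask")
  X <- cbind(field$px[idx], field$py[idx])
  N <- nrow(X)
  nfr <- length(field$mask)
  ps <- field$meta$pixel_spacing
  traj <- array(NA_real_, c(N, 2, nfr))
  valid <- matrix(TRUE, N, nfr)
  traj[, , 1] <- X
  for (k in seq(2L, length.out = nfr - 1L)) {
    s <- field_sites(field, k)
    inv <- local_poly_predict(s$ref, s$x, X, pixel_spacing = ps)
    x_t <- inv$pred
    # residual check: re-evaluate the reference position of x(t)
    fwd <- local_poly_predict(s$x, s$ref, x_t, pixel_spacing = ps)
    res <- sqrt(rowSums((fwd$pred - X)^2))
    ok <- valid[, k - 1] & inv$dist <= max_gap * ps & res < residual_tol * ps
    valid[, k:nfr] <- valid[, k:nfr] & ok   # invalidity is monotone
    traj[, , k] <- x_t
    if (mean(ok) < 0.5)
      stop(sprintf("tracking failure: only %.0f%% of points valid at frame %d",
                   100 * mean(ok), k))
  }
  structure(list(reference = X, traj = traj, valid = valid, meta = field$meta),
            class = "material_points")
}

#' Local least-squares deformation gradient
#'
#' Fits the 2x2 deformation gradient F at one tracked point and frame from
#' the motion of its neighbours: F minimises the sum of squared residuals
#' ||dx - F dX|| over all valid neighbours within \code{radius} of the
#' point's reference position (dX = reference offsets, dx = current
#' offsets). With \code{order = 2} a quadratic motion model is fitted and its
#' linear part taken as F, which removes the first-order bias of the affine
#' fit where strain varies across the neighbourhood; both are exact for
#' affine motion.
#'
#' @param points A \code{\link{track_points}} result.
#' @param index Point index.
#' @param frame Frame index.
#' @param radius Neighbourhood radius, mm (default 4 pixels).
#' @param order Motion-model order (1 = affine, 2 = quadratic, 3 = cubic;
#'   automatically lowered when the neighbourhood is too small to support
#'   it). Higher orders remove the curvature bias of the affine fit where
#'   strain varies across the neighbourhood.
#' @param sigma Gaussian distance-weighting scale, mm (default 2 pixels);
#'   \code{Inf} for unweighted.
#' @return 2x2 matrix F, or NULL when the neighbourhood is rank-deficient or
#'   has fewer than 6 valid neighbours.
#' @export
fit_deformation_gradient <- function(points, index, frame, radius = NULL,
                                     order = 3L, sigma = NULL) {
  stopifnot(inherits(points, "material_points"))
  if (is.null(radius)) radius <- 4 * points$meta$pixel_spacing
  if (is.null(sigma)) sigma <- 2 * points$meta$pixel_spacing
  X0 <- points$reference[index, ]
  dd <- (points$reference[, 1] - X0[1])^2 + (points$reference[, 2] - X0[2])^2
  nb <- which(dd <= radius^2 & points$valid[, frame])
  nb <- setdiff(nb, index)
  w <- if (is.finite(sigma)) exp(-dd[nb] / (2 * sigma^2)) else NULL
  fit_F_from_offsets(points$reference[nb, , drop = FALSE] -
                       matrix(X0, length(nb), 2, byrow = TRUE),
                     points$traj[nb, , frame, drop = FALSE][, , 1] -
                       matrix(points$traj[index, , frame], length(nb), 2,
                              byrow = TRUE),
                     order = order, weights = w)
}

#' @keywords internal
fit_F_from_offsets <- function(dX, dx, order = 2L, weights = NULL) {
  n <- nrow(dX)
  if (is.null(n) || n < 6L) return(NULL)
  # highest model order the neighbourhood supports
  use_order <- if (order >= 3L && n >= 14L) 3L else
    if (order >= 2L && n >= 10L) 2L else 1L
  x1 <- dX[, 1]; x2 <- dX[, 2]
  D <- cbind(x1, x2)
  if (use_order >= 2L) D <- cbind(D, x1^2, x1 * x2, x2^2)
  if (use_order >= 3L) D <- cbind(D, x1^3, x1^2 * x2, x1 * x2^2, x2^3)
  if (!is.null(weights)) {
    D <- D * weights
    dx <- dx * weights
  }
  qrD <- qr(D)
  if (qrD$rank < 2L) return(NULL)
  cf <- tryCatch(qr.coef(qrD, dx), error = function(e) NULL)
  if (is.null(cf) || any(!is.finite(cf[1:2, ]))) return(NULL)
  unname(t(cf[1:2, , drop = FALSE]))  # rows: components; cols: d/dX1, d/dX2
}

#' Green-Lagrange tensor from a deformation gradient
#' @param F 2x2 deformation gradient.
#' @return 2x2 Green-Lagrange strain tensor (F'F - I)/2.
#' @export
green_lagrange <- function(F) (t(F) %*% F - diag(2)) / 2

# Engineering strain (%) along a unit direction from the Green-Lagrange
# tensor: 100 * (sqrt(2 E_dir + 1) - 1).
#' @keywords internal
eng_strain <- function(E_dir) 100 * (sqrt(pmax(2 * E_dir + 1, 0)) - 1)

#' Project a strain tensor onto radial and circumferential directions
#'
#' The radial unit vector points from the (fixed, end-diastolic) centroid to
#' the point's reference position; the circumferential unit vector is its
#' 90-degree counter-clockwise rotation.  Tensor components are converted to
#' engineering percent length change.
#'
#' @param E 2x2 Green-Lagrange tensor.
#' @param reference_position Length-2 reference position, mm.
#' @param centroid Length-2 centroid, mm.
#' @return Named vector \code{c(err = , ecc = )}, engineering \%.
#' @export
#' @examples
#' F <- diag(2) * 1.1
#' project_strain(green_lagrange(F), c(1, 0), c(0, 0))  # err = ecc = 10
project_strain <- function(E, reference_position, centroid) {
  v <- reference_position - centroid
  nv <- sqrt(sum(v^2))
  if (nv < .Machine$double.eps) stop("reference position equals centroid")
  er <- v / nv
  ec <- c(-er[2], er[1])
  c(err = eng_strain(drop(er %*% E %*% er)),
    ecc = eng_strain(drop(ec %*% E %*% ec)))
}

#' Assign wall depth, layer and 16-segment id to tracked points
#'
#' Depth is the normalised distance from endocardium to epicardium along the
#' ray from the end-diastolic epicardial centroid through the point (0 =
#' endocardial surface).  Layers are transmural thirds; segments partition
#' the angle into 6 (basal), 6 (mid) or 4 (apical) equal sectors numbered in
#' the standard 16-segment convention (basal 1-6, mid 7-12, apical 13-16),
#' counting counter-clockwise from the angular origin.
#'
#' @param points A \code{\link{track_points}} result (or an N x 2 matrix of
#'   reference positions).
#' @param contours End-diastolic \code{\link{contour_set}} for the slice.
#' @param slice One of \code{"basal"}, \code{"mid"}, \code{"apical"}.
#' @param origin_angle_deg Angular origin of segment 1's leading edge,
#'   degrees; default -90 (image "up"). The anterior-septal insertion is not
#'   identifiable without the right ventricle, so this origin is a labelling
#'   convention only.
#' @return data.frame with \code{depth}, \code{layer} (factor endo/mid/epi),
#'   \code{segment_id}, \code{theta} (radians), \code{in_wall} (logical;
#'   points outside the annulus are flagged and excluded downstream).
#' @export
assign_layers_segments <- function(points, contours, slice,
                                   origin_angle_deg = -90) {
  slice <- match.arg(slice, short_axis_labels())
  X <- if (inherits(points, "material_points")) points$reference else as.matrix(points)
  cen <- polygon_centroid(contours$epicardium)
  th <- atan2(X[, 2] - cen[2], X[, 1] - cen[1])
  r <- sqrt((X[, 1] - cen[1])^2 + (X[, 2] - cen[2])^2)
  r_en <- polygon_radius_at(contours$endocardium, cen, th)
  r_ep <- polygon_radius_at(contours$epicardium, cen, th)
  depth <- (r - r_en) / (r_ep - r_en)
  in_wall <- depth >= -1e-6 & depth <= 1 + 1e-6
  depth <- pmin(pmax(depth, 0), 1)
  layer <- cut(depth, breaks = c(-Inf, 1 / 3, 2 / 3, Inf),
               labels = c("endo", "mid", "epi"))
  nseg <- if (slice == "apical") 4L else 6L
  offset <- switch(slice, basal = 0L, mid = 6L, apical = 12L)
  rel <- ((th - deg2rad(origin_angle_deg)) %% (2 * pi)) / (2 * pi)
  segment_id <- offset + pmin(floor(rel * nseg), nseg - 1L) + 1L
  data.frame(depth = depth, layer = layer, segment_id = as.integer(segment_id),
             theta = th, in_wall = in_wall)
}

#' Per-point strain samples for one short-axis slice
#'
#' Runs the deformation-gradient fit at every valid tracked point and frame
#' and projects onto radial/circumferential directions defined from the
#' end-diastolic epicardial centroid.  Neighbourhoods (and their least-
#' squares factorisations) are precomputed in the reference configuration
#' and reused across frames.
#'
#' @param points A \code{\link{track_points}} result.
#' @param contours End-diastolic \code{\link{contour_set}}.
#' @param slice Short-axis slice label.
#' @param radius Fit neighbourhood radius, mm (default 4 pixels).
#' @param order Motion-model order passed to the fit (default cubic).
#' @param sigma Gaussian distance-weighting scale, mm (default 2 pixels).
#' @return data.frame with point, frame, frame_time, err, ecc, depth, layer,
#'   segment_id, theta.
#' @export
strain_samples <- function(points, contours, slice, radius = NULL,
                           order = 3L, sigma = NULL) {
  stopifnot(inherits(points, "material_points"))
  if (is.null(radius)) radius <- 4 * points$meta$pixel_spacing
  if (is.null(sigma)) sigma <- 2 * points$meta$pixel_spacing
  X <- points$reference
  N <- nrow(X)
  nfr <- dim(points$traj)[3]
  lay <- assign_layers_segments(points, contours, slice)
  cen <- polygon_centroid(contours$epicardium)

  # reference-frame neighbour lists and weights
  nb_list <- lapply(seq_len(N), function(i) {
    dd <- (X[, 1] - X[i, 1])^2 + (X[, 2] - X[i, 2])^2
    nb <- setdiff(which(dd <= radius^2), i)
    list(nb = nb,
         w = if (is.finite(sigma)) exp(-dd[nb] / (2 * sigma^2)) else NULL)
  })
  all_valid <- matrix(TRUE, N, nfr)
  res <- vector("list", nfr)
  # direction vectors per point
  v <- X - matrix(cen, N, 2, byrow = TRUE)
  nv <- sqrt(rowSums(v^2))
  er <- v / nv
  ec <- cbind(-er[, 2], er[, 1])

  for (k in seq_len(nfr)) {
    err <- rep(NA_real_, N); ecc <- rep(NA_real_, N)
    for (i in seq_len(N)) {
      if (!points$valid[i, k] || !lay$in_wall[i]) next
      keep <- points$valid[nb_list[[i]]$nb, k]
      nb <- nb_list[[i]]$nb[keep]
      if (length(nb) < 6L) next
      w <- nb_list[[i]]$w[keep]
      dX <- X[nb, , drop = FALSE] - matrix(X[i, ], length(nb), 2, byrow = TRUE)
      dx <- points$traj[nb, , k, drop = FALSE][, , 1] -
        matrix(points$traj[i, , k], length(nb), 2, byrow = TRUE)
      F <- fit_F_from_offsets(dX, dx, order = order, weights = w)
      if (is.null(F)) next
      E <- green_lagrange(F)
      err[i] <- eng_strain(drop(er[i, ] %*% E %*% er[i, ]))
      ecc[i] <- eng_strain(drop(ec[i, ] %*% E %*% ec[i, ]))
    }
    res[[k]] <- data.frame(point = seq_len(N), frame = k,
                           frame_time = points$meta$frame_times[k],
                           err = err, ecc = ecc,
                           depth = lay$depth, layer = lay$layer,
                           segment_id = lay$segment_id, theta = lay$theta)
  }
  out <- do.call(rbind, res)
  out[!is.na(out$err) | out$frame == 1, ]
}

#' Peak strain of a curve
#'
#' Peak strain is the extremum of the strain-time curve: the minimum for
#' circumferential/longitudinal strain (maximum shortening) and the maximum
#' for radial strain (maximum thickening).
#'
#' @param curve Numeric strain curve, \%.
#' @param direction One of \code{"circumferential"}, \code{"longitudinal"},
#'   \code{"radial"}.
#' @return Peak strain, \%.
#' @export
#' @examples
#' peak_strain(c(0, -5, -17, -10), "circumferential")  # -17
#' peak_strain(c(0, 10, 36, 20), "radial")             # 36
peak_strain <- function(curve, direction = c("circumferential",
                                             "longitudinal", "radial")) {
  direction <- match.arg(direction)
  if (!length(curve)) stop("empty strain curve")
  if (direction == "radial") max(curve) else min(curve)
}
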