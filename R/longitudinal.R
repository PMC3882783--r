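# Longitudinal strain from the long-axis (two- and four-chamber) slices.

# Distance from points to a closed polygon boundary (min over segments),
# plus the unit tangent of the nearest segment.
#' @keywords internal
nearest_segment <- function(px, py, poly, drop_base = FALSE) {
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  if (drop_base) {
    # the base-plane closure of a long-axis silhouette is not wall: drop
    # segments lying entirely within 2% of the basal extreme
    tol <- 0.02 * diff(range(poly[, 2]))
    base_z <- max(poly[, 2])
    keep <- !(a[, 2] > base_z - tol & b[, 2] > base_z - tol)
    a <- a[keep, , drop = FALSE]
    b <- b[keep, , drop = FALSE]
    n <- nrow(a)
  }
  m <- length(px)
  best_d2 <- rep(Inf, m)
  best_t <- matrix(0, m, 2)
  for (e in seq_len(n)) {
    ex <- b[e, 1] - a[e, 1]; ey <- b[e, 2] - a[e, 2]
    L2 <- ex^2 + ey^2
    if (L2 < 1e-20) next
    t <- pmin(pmax(((px - a[e, 1]) * ex + (py - a[e, 2]) * ey) / L2, 0), 1)
    dx <- px - (a[e, 1] + t * ex); dy <- py - (a[e, 2] + t * ey)
    d2 <- dx^2 + dy^2
    upd <- d2 < best_d2
    if (any(upd)) {
      best_d2[upd] <- d2[upd]
      Ln <- sqrt(L2)
      best_t[upd, 1] <- ex / Ln
      best_t[upd, 2] <- ey / Ln
    }
  }
  list(dist = sqrt(best_d2), tangent = best_t)
}

#' Longitudinal strain from the two long-axis views
#'
#' For each long-axis slice the tracked points are projected onto the local
#' wall-tangent direction (tangent of the nearest epicardial contour
#' segment) to give the longitudinal engineering strain per point and frame.
#' Points in the apical region -- within \code{apex_fraction} of the
#' long-axis length above the apex -- are excluded, since the longitudinal
#' direction is ill-defined where the ventricle curves around the apex.  The
#' reported curve is the mean of the two views' mean curves.
#'
#' @param points_2ch,points_4ch \code{\link{track_points}} results for the
#'   two- and four-chamber slices.
#' @param contours_2ch,contours_4ch End-diastolic \code{\link{contour_set}}s
#'   for those slices.
#' @param apex_fraction Apical exclusion threshold as a fraction of the
#'   long-axis length (default 0.3).
#' @param radius,order,sigma Deformation-gradient fit parameters (see
#'   \code{\link{fit_deformation_gradient}}).
#' @return List with \code{curve} (mean longitudinal strain \% per frame),
#'   \code{per_view} (2 x nframes matrix), \code{layer_curves} (3 x nframes:
#'   endo/mid/epi means), \code{frame_times}.
#' @export
longitudinal_strain <- function(points_2ch, contours_2ch,
                                points_4ch, contours_4ch,
                                apex_fraction = 0.3,
                                radius = NULL, order = 3L, sigma = NULL) {
  if (missing(points_2ch) || missing(points_4ch) ||
      is.null(points_2ch) || is.null(points_4ch))
    stop("both long-axis views are required for longitudinal strain")
  views <- list(list(points = points_2ch, contours = contours_2ch),
                list(points = points_4ch, contours = contours_4ch))
  nfr <- dim(points_2ch$traj)[3]
  per_view <- matrix(NA_real_, 2, nfr)
  layer_acc <- array(NA_real_, c(2, 3, nfr))
  for (vi in 1:2) {
    v <- views[[vi]]
    ell <- ell_samples(v$points, v$contours, apex_fraction, radius, order,
                       sigma)
    per_view[vi, ] <- vapply(seq_len(nfr), function(k)
      mean(ell$value[ell$frame == k], na.rm = TRUE), numeric(1))
    for (li in 1:3) {
      lv <- levels(ell$layer)[li]
      layer_acc[vi, li, ] <- vapply(seq_len(nfr), function(k)
        mean(ell$value[ell$frame == k & ell$layer == lv], na.rm = TRUE),
        numeric(1))
    }
  }
  layer_curves <- apply(layer_acc, c(2, 3), mean)
  rownames(layer_curves) <- c("endo", "mid", "epi")
  list(curve = colMeans(per_view), per_view = per_view,
       layer_curves = layer_curves,
       frame_times = points_2ch$meta$frame_times)
}

# Per-point longitudinal strain samples for one long-axis view.
#' @keywords internal
ell_samples <- function(points, contours, apex_fraction = 0.3,
                        radius = NULL, order = 3L, sigma = NULL) {
  if (is.null(radius)) radius <- 4 * points$meta$pixel_spacing
  if (is.null(sigma)) sigma <- 2 * points$meta$pixel_spacing
  X <- points$reference
  N <- nrow(X)
  nfr <- dim(points$traj)[3]
  # apical exclusion along the long axis (vertical image direction)
  apex_z <- min(contours$epicardium[, 2])
  base_z <- max(contours$epicardium[, 2])
  include <- X[, 2] >= apex_z + apex_fraction * (base_z - apex_z)
  # wall tangent from the nearest epicardial wall segment
  tng <- nearest_segment(X[, 1], X[, 2], contours$epicardium,
                         drop_base = TRUE)$tangent
  # wall depth from relative distance to the two silhouettes
  d_en <- nearest_segment(X[, 1], X[, 2], contours$endocardium)$dist
  d_ep <- nearest_segment(X[, 1], X[, 2], contours$epicardium)$dist
  depth <- d_en / pmax(d_en + d_ep, 1e-12)
  layer <- cut(depth, breaks = c(-Inf, 1 / 3, 2 / 3, Inf),
               labels = c("endo", "mid", "epi"))

  nb_list <- lapply(seq_len(N), function(i) {
    dd <- (X[, 1] - X[i, 1])^2 + (X[, 2] - X[i, 2])^2
    nb <- setdiff(which(dd <= radius^2), i)
    list(nb = nb,
         w = if (is.finite(sigma)) exp(-dd[nb] / (2 * sigma^2)) else NULL)
  })
  res <- vector("list", nfr)
  for (k in seq_len(nfr)) {
    val <- rep(NA_real_, N)
    for (i in which(include)) {
      if (!points$valid[i, k]) next
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
      el <- tng[i, ]
      val[i] <- eng_strain(drop(el %*% E %*% el))
    }
    res[[k]] <- data.frame(point = seq_len(N), frame = k, value = val,
                           layer = layer)
  }
  do.call(rbind, res)
}
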