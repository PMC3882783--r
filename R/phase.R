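# Wrapped-phase handling: wrap/unwrap/decode, per-slice displacement fields,
# and motion-guided contour propagation.

#' Wrap phase into (-pi, pi]
#'
#' @param phase Numeric vector/array, radians.
#' @return Values congruent to the input modulo 2*pi, in (-pi, pi].
#' @export
#' @examples
#' wrap_phase(1.4 * pi)   # -0.6 * pi
#' wrap_phase(pi)         # +pi (boundary maps to +pi)
wrap_phase <- function(phase) {
  if (any(!is.finite(phase))) stop("phase must be finite")
  out <- phase - 2 * pi * floor(phase / (2 * pi) + 0.5)
  # floor(.5 + x) rounds half up, so exactly -pi can appear; fold it to +pi
  out[out <= -pi] <- pi
  out
}

#' Quality-guided 2-D phase unwrapping over a masked region
#'
#' Region-growing unwrapper: pixels are absorbed in order of a quality score
#' (negative variance of the wrapped phase gradients to masked neighbours,
#' i.e. smooth regions first), starting from the highest-quality seed.  Each
#' new pixel is unwrapped against the mean of its already-solved neighbours.
#' The result equals the true smooth field up to a single global multiple of
#' 2*pi; ties in quality are broken by row-major pixel index, so the output
#' is deterministic.
#'
#' @param wrapped 2-D matrix of wrapped phase, radians.
#' @param mask Logical matrix of the same size; must be one 4-connected
#'   region.
#' @return Matrix with unwrapped phase on the mask (NA elsewhere).
#' @export
unwrap_masked <- function(wrapped, mask) {
  stopifnot(is.matrix(wrapped), is.logical(mask),
            identical(dim(wrapped), dim(mask)))
  if (!any(mask)) stop("empty mask")
  lab <- label_components(mask)
  ncomp <- max(lab)
  if (ncomp > 1L)
    stop(sprintf("%d connected components in mask; expected 1", ncomp))

  nr <- nrow(wrapped); nc <- ncol(wrapped)
  idx <- which(mask)
  # quality: negative variance of wrapped first differences to masked
  # 4-neighbours (fewer than 2 neighbours -> worst quality)
  neighbours <- function(p) {
    r <- ((p - 1L) %% nr) + 1L
    cc <- ((p - 1L) %/% nr) + 1L
    nb <- integer(0)
    if (r > 1L) nb <- c(nb, p - 1L)
    if (r < nr) nb <- c(nb, p + 1L)
    if (cc > 1L) nb <- c(nb, p - nr)
    if (cc < nc) nb <- c(nb, p + nr)
    nb[mask[nb]]
  }
  quality <- rep(-Inf, nr * nc)
  for (p in idx) {
    nb <- neighbours(p)
    if (length(nb) >= 2L) {
      g <- wrap_phase(wrapped[nb] - wrapped[p])
      quality[p] <- -stats::var(g)
    } else if (length(nb) == 1L) {
      quality[p] <- -4 * pi^2   # poor but usable
    }
  }

  out <- matrix(NA_real_, nr, nc)
  solved <- matrix(FALSE, nr, nc)
  seed <- idx[order(-quality[idx], idx)][1]
  out[seed] <- wrapped[seed]
  solved[seed] <- TRUE
  frontier <- neighbours(seed)

  while (length(frontier)) {
    q <- quality[frontier]
    best <- frontier[order(-q, frontier)][1]
    frontier <- frontier[frontier != best]
    nb <- neighbours(best)
    nb_solved <- nb[solved[nb]]
    pred <- mean(out[nb_solved])
    out[best] <- pred + wrap_phase(wrapped[best] - pred)
    solved[best] <- TRUE
    new <- nb[!solved[nb] & !(nb %in% frontier)]
    frontier <- c(frontier, new)
  }
  out
}

#' Decode unwrapped displacement phase into displacement
#'
#' Displacement = phase / (2 * pi * ke): a linear map, so zero phase decodes
#' to zero displacement and the maximum unambiguous displacement at encoding
#' frequency ke is 1 / (2 * ke) mm.
#'
#' @param phase Unwrapped phase (radians), any shape.
#' @param ke Encoding frequency, cycles/mm; must be positive.
#' @return Displacement in mm, same shape.
#' @export
#' @examples
#' decode_displacement(pi, ke = 1.0)   # 0.5 mm
decode_displacement <- function(phase, ke) {
  if (!is.numeric(ke) || length(ke) != 1L || !is.finite(ke) || ke <= 0)
    stop("ke must be a positive scalar (cycles/mm)")
  phase / (2 * pi * ke)
}

#' Displacement field of one cine DENSE slice
#'
#' Unwraps both phase channels within the per-frame myocardial mask (taken
#' from the magnitude image), resolves each frame's global 2*pi offset by
#' temporal consistency with the previous frame (anchored at frame 1, where
#' displacement is identically zero), and decodes to mm.
#'
#' @param slice A \code{\link{dense_slice}}.
#' @param mask_threshold Magnitude threshold (fraction of the frame maximum)
#'   defining the myocardial mask.
#' @return Object of class \code{displacement_field}: list with per-frame
#'   \code{mask} (logical matrices), \code{ux}, \code{uy} (mm, NA outside the
#'   mask), pixel coordinate matrices \code{px}, \code{py} (mm), and
#'   \code{meta}.
#' @export
compute_displacement_field <- function(slice, mask_threshold = 0.5) {
  stopifnot(inherits(slice, "dense_slice"))
  meta <- slice$meta
  nfr <- dim(slice$magnitude)[3]
  n <- dim(slice$magnitude)[1]
  ps <- meta$pixel_spacing
  coord <- (seq_len(n) - 0.5) * ps
  px <- matrix(coord, n, n, byrow = TRUE)
  py <- matrix(coord, n, n)

  masks <- vector("list", nfr)
  ux <- vector("list", nfr)
  uy <- vector("list", nfr)
  prev <- list(x = NULL, y = NULL)
  for (k in seq_len(nfr)) {
    m <- slice$magnitude[, , k] > mask_threshold * max(slice$magnitude[, , k])
    masks[[k]] <- m
    if (k == 1L) {
      # end-diastolic reference: displacement identically zero
      ux[[k]] <- ifelse(m, 0, NA_real_)
      uy[[k]] <- ifelse(m, 0, NA_real_)
      prev <- list(x = ux[[k]] * 2 * pi * meta$ke,
                   y = uy[[k]] * 2 * pi * meta$ke)
      next
    }
    phx <- unwrap_masked(slice$phase_x[, , k], m)
    phy <- unwrap_masked(slice$phase_y[, , k], m)
    phx <- anchor_offset(phx, prev$x, m)
    phy <- anchor_offset(phy, prev$y, m)
    ux[[k]] <- decode_displacement(phx, meta$ke)
    uy[[k]] <- decode_displacement(phy, meta$ke)
    prev <- list(x = phx, y = phy)
  }
  structure(list(mask = masks, ux = ux, uy = uy, px = px, py = py,
                 meta = meta),
            class = "displacement_field")
}

# Choose the global 2*pi multiple making `phase` most consistent with the
# previous frame's unwrapped field over their common support (falls back to
# minimising the mean phase when the masks do not overlap).
#' @keywords internal
anchor_offset <- function(phase, prev_phase, mask) {
  common <- mask & !is.na(prev_phase) & !is.na(phase)
  k <- if (any(common)) {
    round(mean(prev_phase[common] - phase[common]) / (2 * pi))
  } else {
    -round(mean(phase[mask], na.rm = TRUE) / (2 * pi))
  }
  phase + 2 * pi * k
}

# ---- scattered local polynomial interpolation ------------------------------

# Predict values `val` (n x d) known at scattered 2-D sites `sites` (n x 2)
# at query points `query` (m x 2), by a local least-squares polynomial fit
# (order 2 where enough neighbours, else order 1) over all sites within
# `radius` pixels (a purely geometric selection rule, so the interpolation
# respects the symmetries of the sampling grid; falls back to the 6 nearest
# sites in sparse spots).  Returns list(pred = m x d, dist = nearest-site
# distance per query).
#' @keywords internal
local_poly_predict <- function(sites, val, query, radius = NULL, order = 2L,
                               pixel_spacing = NULL) {
  sites <- as.matrix(sites); query <- as.matrix(query)
  val <- as.matrix(val)
  m <- nrow(query); d <- ncol(val)
  pred <- matrix(NA_real_, m, d)
  ndist <- rep(NA_real_, m)
  n <- nrow(sites)
  if (is.null(radius)) {
    if (is.null(pixel_spacing)) {
      # estimate grid spacing from the nearest-neighbour distance of a site
      dd0 <- (sites[, 1] - sites[1, 1])^2 + (sites[, 2] - sites[1, 2])^2
      pixel_spacing <- sqrt(min(dd0[dd0 > 0]))
    }
    radius <- 2.5 * pixel_spacing
  }
  r2 <- radius^2
  for (i in seq_len(m)) {
    dx <- sites[, 1] - query[i, 1]
    dy <- sites[, 2] - query[i, 2]
    dd <- dx * dx + dy * dy
    nb <- which(dd <= r2)
    if (length(nb) < 6L) nb <- order(dd)[seq_len(min(6L, n))]
    ndist[i] <- sqrt(min(dd[nb]))
    k <- length(nb)
    X1 <- dx[nb]; X2 <- dy[nb]
    use_order <- if (order >= 2L && k >= 10L) 2L else 1L
    D <- if (use_order == 2L) {
      cbind(1, X1, X2, X1 * X1, X1 * X2, X2 * X2)
    } else {
      cbind(1, X1, X2)
    }
    fit <- tryCatch(qr.coef(qr(D), val[nb, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(fit[1, ]))) {
      # rank-deficient neighbourhood: fall back to nearest site
      pred[i, ] <- val[nb[1], ]
    } else {
      pred[i, ] <- fit[1, ]
    }
  }
  list(pred = pred, dist = ndist)
}

# Scattered sites (deformed pixel positions x_i, their reference positions
# X_i = x_i - u_i) for one frame of a displacement field.
#' @keywords internal
field_sites <- function(field, frame) {
  m <- field$mask[[frame]]
  idx <- which(m)
  x <- cbind(field$px[idx], field$py[idx])
  u <- cbind(field$ux[[frame]][idx], field$uy[[frame]][idx])
  list(x = x, ref = x - u, u = u)
}

#' Propagate end-diastolic contours through the cardiac cycle
#'
#' Motion-guided segmentation: each end-diastolic vertex V is moved to the
#' frame-t position x solving x - u(x, t) = V, by local polynomial inverse
#' interpolation of the scattered displacement samples.  Vertices with no
#' displacement sample near their reference position are flagged; more than
#' 10\% flagged vertices in a frame is an error.
#'
#' @param ed_contours A \code{\link{contour_set}} at end-diastole.
#' @param field A \code{\link{compute_displacement_field}} result for the
#'   same slice.
#' @param max_gap Maximum allowed distance (in pixels) from a vertex to the
#'   nearest reference sample.
#' @return List of \code{contour_set} objects, one per frame.
#' @export
propagate_contours <- function(ed_contours, field, max_gap = 2.5) {
  stopifnot(inherits(ed_contours, "contour_set"),
            inherits(field, "displacement_field"))
  nfr <- length(field$mask)
  ps <- field$meta$pixel_spacing
  out <- vector("list", nfr)
  out[[1]] <- ed_contours
  for (k in seq(2L, length.out = nfr - 1L)) {
    s <- field_sites(field, k)
    move <- function(poly) {
      p <- local_poly_predict(s$ref, s$x, poly, pixel_spacing = ps)
      bad <- p$dist > max_gap * ps
      if (mean(bad) > 0.10)
        stop(sprintf("contour propagation failed at frame %d: %.0f%% of vertices unreachable",
                     k, 100 * mean(bad)))
      if (any(bad)) {
        # keep flagged vertices at their previous-frame position
        prev <- if (k == 2L) poly else NULL
        p$pred[bad, ] <- poly[bad, , drop = FALSE]
      }
      p$pred
    }
    out[[k]] <- contour_set(move(ed_contours$endocardium),
                            move(ed_contours$epicardium),
                            frame_index = k)
  }
  out
}
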