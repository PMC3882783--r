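# Small planar-geometry helpers shared across modules.  Polygons are n x 2
# matrices of (x, y) vertices in mm, implicitly closed (last vertex connects
# back to the first).

#' @keywords internal
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

# Signed area: positive for counter-clockwise vertex order.
#' @keywords internal
polygon_signed_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' @keywords internal
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(poly))
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

# Even-odd (crossing number) point-in-polygon test, vectorised over points.
# Points on an edge may land either way; callers needing tolerance should
# inset/outset the polygon.
#' @keywords internal
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  inside <- logical(length(px))
  for (e in seq_len(n)) {
    crosses <- ((y1[e] > py) != (y2[e] > py))
    if (any(crosses)) {
      xint <- x1[e] + (py[crosses] - y1[e]) / (y2[e] - y1[e]) * (x2[e] - x1[e])
      flip <- px[crosses] < xint
      idx <- which(crosses)[flip]
      inside[idx] <- !inside[idx]
    }
  }
  inside
}

# Self-intersection test by brute-force segment pairs (fine for contour sizes
# used here).  Shared endpoints between adjacent segments are ignored.
#' @keywords internal
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  p1 <- poly
  p2 <- poly[c(2:n, 1), , drop = FALSE]
  seg_int <- function(a1, a2, b1, b2) {
    d1 <- a2 - a1; d2 <- b2 - b1
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-14) return(FALSE)
    t <- ((b1[1] - a1[1]) * d2[2] - (b1[2] - a1[2]) * d2[1]) / den
    u <- ((b1[1] - a1[1]) * d1[2] - (b1[2] - a1[2]) * d1[1]) / den
    t > 1e-10 && t < 1 - 1e-10 && u > 1e-10 && u < 1 - 1e-10
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (seg_int(p1[i, ], p2[i, ], p1[j, ], p2[j, ]))
        return(FALSE)
    }
  }
  TRUE
}

# Radius of a star-shaped polygon along a ray from `center` at angle `theta`
# (radians), by linear interpolation of vertices in polar coordinates.
#' @keywords internal
polygon_radius_at <- function(poly, center, theta) {
  ang <- atan2(poly[, 2] - center[2], poly[, 1] - center[1])
  rad <- sqrt((poly[, 1] - center[1])^2 + (poly[, 2] - center[2])^2)
  o <- order(ang)
  ang <- ang[o]; rad <- rad[o]
  ang <- c(ang, ang[1] + 2 * pi)
  rad <- c(rad, rad[1])
  th <- ((theta - ang[1]) %% (2 * pi)) + ang[1]
  i <- findInterval(th, ang, all.inside = TRUE)
  w <- (th - ang[i]) / (ang[i + 1] - ang[i])
  rad[i] * (1 - w) + rad[i + 1] * w
}

# Connected components of a logical image under 4-connectivity.  Returns an
# integer matrix (0 = background).
#' @keywords internal
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      nb <- integer(0)
      if (r > 1L) nb <- c(nb, p - 1L)
      if (r < nr) nb <- c(nb, p + 1L)
      if (cc > 1L) nb <- c(nb, p - nr)
      if (cc < nc) nb <- c(nb, p + nr)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  lab
}

#' @keywords internal
deg2rad <- function(x) x * pi / 180

#' @keywords internal
rad2deg <- function(x) x * 180 / pi
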