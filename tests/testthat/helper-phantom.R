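# Shared fixtures: the packaged phantom configurations, rendered and
# analysed once per test run (the heavy pipeline results are cached).

.fixture_cache <- new.env(parent = emptyenv())

lowfat_config <- function() {
  phantom_config_from_yaml(
    system.file("extdata", "lowfat.yaml", package = "cinedense"))
}

highfat_config <- function() {
  phantom_config_from_yaml(
    system.file("extdata", "highfat.yaml", package = "cinedense"))
}

lowfat_fixture <- function() {
  if (is.null(.fixture_cache$lowfat)) {
    cfg <- lowfat_config()
    rs <- render_study(cfg)
    .fixture_cache$lowfat <- list(cfg = cfg, study = rs$study,
                                  truth = rs$truth,
                                  analysis = analyze_study(rs$study))
  }
  .fixture_cache$lowfat
}

highfat_fixture <- function() {
  if (is.null(.fixture_cache$highfat)) {
    cfg <- highfat_config()
    rs <- render_study(cfg)
    .fixture_cache$highfat <- list(cfg = cfg, study = rs$study,
                                   truth = rs$truth,
                                   analysis = analyze_study(rs$study))
  }
  .fixture_cache$highfat
}

# A small, quick-to-render phantom for IO round-trips and similar tests.
small_config <- function(...) {
  phantom_config(field_of_view = 16, matrix_size = 64, heart_rate = 1200,
                 ...)   # 7 frames at TR 7.1
}

# Synthetic tracked-point set undergoing a prescribed affine (or general)
# motion: reference grid points in an annulus, trajectories mapped by `f`
# per frame (f(X, frame) -> matrix).
synthetic_points <- function(f, n_frames = 3, spacing = 0.25,
                             r_in = 1.2, r_out = 2.4) {
  g <- seq(-r_out, r_out, by = spacing)
  X <- as.matrix(expand.grid(x = g, y = g))
  r <- sqrt(rowSums(X^2))
  X <- X[r >= r_in & r <= r_out, ]
  X <- X + matrix(c(16, 16), nrow(X), 2, byrow = TRUE)
  traj <- array(NA_real_, c(nrow(X), 2, n_frames))
  for (k in seq_len(n_frames)) traj[, , k] <- f(X, k)
  meta <- acquisition_meta(ke = 1, field_of_view = 32,
                           matrix_size = round(32 / spacing), tr = 7.1,
                           frame_times = (seq_len(n_frames) - 1) * 7.1)
  structure(list(reference = X, traj = traj,
                 valid = matrix(TRUE, nrow(X), n_frames), meta = meta),
            class = "material_points")
}

# A dense_slice whose phase channels encode a spatially uniform in-plane
# translation (ux, uy) ramping linearly over frames, with a disk-annulus
# magnitude mask.
translation_slice <- function(ux, uy, n_frames = 4, n = 64, fov = 16,
                              ke = 1) {
  ps <- fov / n
  coord <- (seq_len(n) - 0.5) * ps
  px <- matrix(coord, n, n, byrow = TRUE)
  py <- matrix(coord, n, n)
  cen <- fov / 2
  r <- sqrt((px - cen)^2 + (py - cen)^2)
  mask <- r >= 1.2 & r <= 2.4
  dims <- c(n, n, n_frames)
  mag <- array(0, dims); phx <- array(0, dims); phy <- array(0, dims)
  for (k in seq_len(n_frames)) {
    s <- (k - 1) / (n_frames - 1)
    m <- matrix(0, n, n); m[mask] <- 1
    fx <- matrix(0, n, n); fy <- matrix(0, n, n)
    fx[mask] <- wrap_phase(2 * pi * ke * ux * s)
    fy[mask] <- wrap_phase(2 * pi * ke * uy * s)
    mag[, , k] <- m; phx[, , k] <- fx; phy[, , k] <- fy
  }
  meta <- acquisition_meta(ke = ke, field_of_view = fov, matrix_size = n,
                           tr = 7.1, frame_times = (seq_len(n_frames) - 1) * 7.1)
  dense_slice("mid", mag, phx, phy, meta, slice_position = 4)
}

# Circular contour helper.
circle_contour <- function(r, center = c(16, 16), n = 72) {
  th <- (seq_len(n) - 1) * 2 * pi / n
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}
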