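# Analytic left-ventricular deformation phantom.
#
# Geometry: the end-diastolic LV is a half-ellipsoid of revolution about the
# long axis (z, mm above the epicardial apex).  Endocardial and epicardial
# radius profiles are
#     r_endo(z) = R_nb * sqrt(zeta * (2 - zeta)),  zeta  = (z - t_a) / (L - t_a)
#     r_epi(z)  = R_eb * sqrt(zetae * (2 - zetae)), zetae = z / L
# with L the epicardial long-axis length, t_a the apical wall thickness, and
# base radii R_nb, R_eb derived from the configured mid-ventricular radii.
#
# Deformation: each material ring at reference radius R and wall depth d
# contracts to radius lambda_c(d, t) * R, where the peak circumferential
# stretch interpolates linearly in depth anchored at the *layer centres*
# (depth 1/6 -> circ_stretch_endo, depth 5/6 -> circ_stretch_epi), so the
# configured stretches are the subendocardial / subepicardial layer values as
# strain tables report them.  Short-axis planes additionally rotate by a twist
# angle linear in z between the basal and apical slice positions; long-axis
# planes additionally contract longitudinally toward the apex with stretch
# lambda_l(t).  All motion is modulated by a smooth raised-cosine activation
# envelope with per-sector onset delays (the dyssynchrony control).

#' Phantom configuration
#'
#' Full ground-truth specification of the synthetic LV: geometry, transmural
#' peak stretches, twist, activation delays, timing, noise and seed.
#'
#' @param endo_radius_ed,epi_radius_ed End-diastolic endo/epicardial radii at
#'   the mid-ventricular slice, mm.
#' @param long_axis_length_ed End-diastolic epicardial long-axis length, mm.
#' @param apex_wall_thickness Apical wall thickness, mm.
#' @param circ_stretch_endo,circ_stretch_epi Peak circumferential stretch of
#'   the subendocardial / subepicardial layer (dimensionless; 0.83 means -17%
#'   engineering strain).
#' @param long_stretch Peak longitudinal stretch (e.g. 0.88 for -12%).
#' @param twist_base_peak,twist_apex_peak Peak twist (degrees,
#'   counter-clockwise viewed from the apex positive) at the basal and apical
#'   image slices; twist varies linearly in z between them.
#' @param delay_amplitude_ms Septal-to-lateral activation delay amplitude, ms:
#'   onset delay is \code{amp * (1 - cos(theta - septum))/2}, zero at the
#'   septum, maximal at the lateral wall.
#' @param septum_angle_deg Angular position of the septum in the short-axis
#'   image plane, degrees (default 180 = image left).
#' @param heart_rate Beats per minute.
#' @param systole_ms Time from activation onset to peak contraction, ms.
#' @param ke,field_of_view,matrix_size,tr Acquisition parameters (see
#'   \code{\link{acquisition_meta}}).
#' @param phase_noise_sd Gaussian phase noise standard deviation, radians.
#' @param random_seed Integer seed used by \code{\link{render_study}}.
#' @return Object of class \code{phantom_config}.
#' @export
phantom_config <- function(endo_radius_ed = 1.41, epi_radius_ed = 2.26,
                           long_axis_length_ed = 10.0,
                           apex_wall_thickness = 1.0,
                           circ_stretch_endo = 0.83, circ_stretch_epi = 0.906,
                           long_stretch = 0.88,
                           twist_base_peak = 0, twist_apex_peak = 8.8,
                           delay_amplitude_ms = 0, septum_angle_deg = 180,
                           heart_rate = 457, systole_ms = 49.7,
                           ke = 1.0, field_of_view = 32, matrix_size = 128,
                           tr = 7.1, phase_noise_sd = 0, random_seed = 1L) {
  if (!(endo_radius_ed > 0 && epi_radius_ed > endo_radius_ed))
    stop("require epi_radius_ed > endo_radius_ed > 0")
  for (s in c(circ_stretch_endo, circ_stretch_epi, long_stretch))
    if (!(s > 0 && s <= 1))
      stop("stretches must lie in (0, 1]")
  if (phase_noise_sd < 0) stop("phase_noise_sd must be >= 0")
  if (heart_rate <= 0) stop("heart_rate must be positive")
  n_frames <- floor(60000 / heart_rate / tr)
  cfg <- structure(list(
    endo_radius_ed = endo_radius_ed, epi_radius_ed = epi_radius_ed,
    long_axis_length_ed = long_axis_length_ed,
    apex_wall_thickness = apex_wall_thickness,
    circ_stretch_endo = circ_stretch_endo, circ_stretch_epi = circ_stretch_epi,
    long_stretch = long_stretch,
    twist_base_peak = twist_base_peak, twist_apex_peak = twist_apex_peak,
    delay_amplitude_ms = delay_amplitude_ms,
    septum_angle_deg = septum_angle_deg,
    heart_rate = heart_rate, systole_ms = systole_ms,
    ke = ke, field_of_view = field_of_view,
    matrix_size = as.integer(matrix_size), tr = tr,
    phase_noise_sd = phase_noise_sd, random_seed = as.integer(random_seed),
    n_frames = n_frames
  ), class = "phantom_config")
  cfg
}

#' Load a phantom configuration from a YAML file
#'
#' The package ships \code{lowfat.yaml} and \code{highfat.yaml} under
#' \code{inst/extdata}, transcribed from the printed group means of the
#' low-fat and high-fat diet cohorts.
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   \code{\link{phantom_config}}.
#' @return A \code{\link{phantom_config}}.
#' @export
#' @examples
#' cfg <- phantom_config_from_yaml(
#'   system.file("extdata", "lowfat.yaml", package = "cinedense"))
phantom_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(phantom_config, vals)
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf("LV phantom: lambda_c endo/epi %.3g/%.3g, lambda_l %.3g\n",
              x$circ_stretch_endo, x$circ_stretch_epi, x$long_stretch))
  cat(sprintf("  twist base/apex %.3g/%.3g deg over %.3g mm; HR %g bpm, %d frames\n",
              x$twist_base_peak, x$twist_apex_peak, x$long_axis_length_ed,
              x$heart_rate, x$n_frames))
  cat(sprintf("  delay amplitude %g ms; phase noise sd %g rad; seed %d\n",
              x$delay_amplitude_ms, x$phase_noise_sd, x$random_seed))
  invisible(x)
}

#' Short-axis slice planning from the end-systolic long-axis length
#'
#' The mid-ventricular slice sits 50\% of the end-systolic long-axis length
#' above the apex; the basal and apical slices sit 20\% of that length above
#' and below the mid-ventricle.
#'
#' @param long_axis_length_es End-systolic long-axis length, mm.
#' @return Named numeric vector \code{c(basal=, mid=, apical=)} of slice
#'   heights above the apex, mm.
#' @export
#' @examples
#' plan_slices(8)   # basal 5.6, mid 4.0, apical 2.4
plan_slices <- function(long_axis_length_es) {
  if (!is.numeric(long_axis_length_es) || long_axis_length_es <= 0)
    stop("long-axis length must be positive")
  c(basal = 0.7, mid = 0.5, apical = 0.3) * long_axis_length_es
}

#' Raised-cosine activation envelope
#'
#' Temporal contraction envelope for one wall sector: zero until the onset
#' delay, rising as a raised cosine to peak 1 at \code{delay + systole_ms},
#' then relaxing back to zero by the end of the cardiac cycle.  Continuous
#' in t.
#'
#' @param t Time, ms from the R-wave (vectorised).
#' @param delay Activation onset delay, ms.
#' @param period Cardiac cycle length, ms.
#' @param systole_ms Onset-to-peak interval, ms.
#' @return Envelope values in [0, 1].
#' @export
activation <- function(t, delay, period, systole_ms = 49.7) {
  if (period <= 0) stop("period must be positive")
  n <- max(length(t), length(delay))
  t <- rep_len(as.numeric(t), n)
  delay <- rep_len(as.numeric(delay), n)
  tp <- delay + systole_ms
  out <- numeric(n)
  up <- t > delay & t <= tp
  out[up] <- 0.5 * (1 - cos(pi * (t[up] - delay[up]) / systole_ms))
  rel <- period - tp
  dn <- t > tp & t < period & rel > 0
  out[dn] <- 0.5 * (1 + cos(pi * (t[dn] - tp[dn]) / rel[dn]))
  out
}

# ---- internal geometry ------------------------------------------------------

#' @keywords internal
phantom_geometry <- function(cfg) {
  L <- cfg$long_axis_length_ed
  ta <- cfg$apex_wall_thickness
  les <- cfg$long_stretch * L                      # end-systolic length
  zs <- plan_slices(les)                           # slice heights above apex
  zmid <- zs[["mid"]]
  zeta <- (zmid - ta) / (L - ta)
  zetae <- zmid / L
  R_nb <- cfg$endo_radius_ed / sqrt(zeta * (2 - zeta))
  R_eb <- cfg$epi_radius_ed / sqrt(zetae * (2 - zetae))
  center <- rep(cfg$field_of_view / 2, 2)          # SA in-plane center, mm
  la_origin <- c(cfg$field_of_view / 2,            # LA: apex at this image y
                 cfg$field_of_view / 2 - L / 2)
  list(L = L, ta = ta, R_nb = R_nb, R_eb = R_eb, slice_z = zs,
       center = center, la_origin = la_origin, period = 60000 / cfg$heart_rate)
}

#' @keywords internal
endo_radius_at <- function(geo, z) {
  zeta <- pmin(pmax((z - geo$ta) / (geo$L - geo$ta), 0), 1)
  geo$R_nb * sqrt(zeta * (2 - zeta))
}

#' @keywords internal
epi_radius_at <- function(geo, z) {
  zetae <- pmin(pmax(z / geo$L, 0), 1)
  geo$R_eb * sqrt(zetae * (2 - zetae))
}

# Peak circumferential stretch as a function of wall depth d in [0, 1]
# (0 = endocardial surface), anchored at the layer centres d = 1/6 and 5/6.
#' @keywords internal
peak_circ_stretch <- function(cfg, d) {
  cfg$circ_stretch_endo +
    (d - 1 / 6) * 1.5 * (cfg$circ_stretch_epi - cfg$circ_stretch_endo)
}

# Sector activation delay, ms, as a function of reference angle (radians).
#' @keywords internal
sector_delay <- function(cfg, theta) {
  if (cfg$delay_amplitude_ms == 0) return(rep(0, length(theta)))
  cfg$delay_amplitude_ms *
    (1 - cos(theta - deg2rad(cfg$septum_angle_deg))) / 2
}

# Peak twist (degrees) at height z: linear in z through the basal and apical
# slice positions.
#' @keywords internal
peak_twist_at <- function(cfg, geo, z) {
  za <- geo$slice_z[["apical"]]; zb <- geo$slice_z[["basal"]]
  cfg$twist_apex_peak +
    (z - za) / (zb - za) * (cfg$twist_base_peak - cfg$twist_apex_peak)
}

# ---- forward material map ---------------------------------------------------

#' Phantom material map: reference to deformed position
#'
#' Maps end-diastolic (reference) in-plane positions to their deformed
#' positions at time \code{t}, for one slice.  Short-axis slices apply the
#' transmural circumferential contraction plus slice twist; long-axis slices
#' apply the circumferential contraction (as motion of the ring radius
#' \code{|h|}) plus longitudinal contraction toward the apex.  Points must
#' lie inside the end-diastolic myocardium of their slice.
#'
#' @param cfg A \code{\link{phantom_config}}.
#' @param X n x 2 matrix of reference positions, mm, in image coordinates.
#' @param slice Slice label (one of \code{slice_labels()}).
#' @param t Time, ms.
#' @return n x 2 matrix of deformed positions, mm.
#' @export
material_map <- function(cfg, X, slice, t) {
  geo <- phantom_geometry(cfg)
  X <- matrix(as.numeric(X), ncol = 2)
  if (slice %in% short_axis_labels()) {
    z <- geo$slice_z[[slice]]
    dx <- X[, 1] - geo$center[1]; dy <- X[, 2] - geo$center[2]
    R <- sqrt(dx^2 + dy^2); Th <- atan2(dy, dx)
    re <- endo_radius_at(geo, z); rp <- epi_radius_at(geo, z)
    if (any(R < re - 1e-9 | R > rp + 1e-9))
      stop("reference point outside the end-diastolic annulus")
    d <- (R - re) / (rp - re)
    a <- activation(t, sector_delay(cfg, Th), geo$period, cfg$systole_ms)
    lam <- 1 + (peak_circ_stretch(cfg, d) - 1) * a
    tw <- deg2rad(peak_twist_at(cfg, geo, z)) * a
    r <- lam * R
    cbind(geo$center[1] + r * cos(Th + tw), geo$center[2] + r * sin(Th + tw))
  } else {
    h <- X[, 1] - geo$la_origin[1]
    z <- X[, 2] - geo$la_origin[2]
    theta_side <- la_side_angle(slice, h)
    re <- endo_radius_at(geo, z); rp <- epi_radius_at(geo, z)
    R <- abs(h)
    if (any(R < re - 1e-9 | R > rp + 1e-9 | z < -1e-9 | z > geo$L + 1e-9))
      stop("reference point outside the end-diastolic myocardium")
    d <- (R - re) / pmax(rp - re, 1e-12)
    a <- activation(t, sector_delay(cfg, theta_side), geo$period, cfg$systole_ms)
    lam_c <- 1 + (peak_circ_stretch(cfg, d) - 1) * a
    lam_l <- 1 + (cfg$long_stretch - 1) * a
    cbind(geo$la_origin[1] + sign(h) * lam_c * R,
          geo$la_origin[2] + lam_l * z)
  }
}

# Angular position represented by each side of a long-axis image.
#' @keywords internal
la_side_angle <- function(slice, h) {
  if (slice == "four_chamber") ifelse(h >= 0, 0, pi) else
    ifelse(h >= 0, pi / 2, -pi / 2)
}

# ---- analytic strains and ground truth -------------------------------------

# Analytic peak engineering strains (%) at wall depth d for a short-axis
# slice at height z: circumferential from lambda_c, radial from dr/dR.
#' @keywords internal
analytic_peak_strains <- function(cfg, geo, z, d) {
  re <- endo_radius_at(geo, z); rp <- epi_radius_at(geo, z)
  W <- rp - re
  R <- re + d * W
  lam <- peak_circ_stretch(cfg, d)
  dlam_dR <- 1.5 * (cfg$circ_stretch_epi - cfg$circ_stretch_endo) / W
  list(ecc = 100 * (lam - 1),
       err = 100 * (lam + R * dlam_dR - 1))
}

#' Analytic per-sector strain curves of the phantom
#'
#' Mid-wall sector strain versus frame time for N equal angular sectors of
#' one short-axis slice, computed in closed form from the deformation model
#' (no image rendering).  These are the curves the uniformity indices and the
#' dyssynchrony calibration are defined on.
#'
#' @param cfg A \code{\link{phantom_config}}.
#' @param slice Short-axis slice label.
#' @param direction \code{"circumferential"} or \code{"radial"}.
#' @param n_sectors Number of equal angular sectors.
#' @return \code{n_sectors x n_frames} matrix of engineering strain, \%.
#' @export
analytic_sector_curves <- function(cfg, slice = "mid",
                                   direction = c("circumferential", "radial"),
                                   n_sectors = 24) {
  direction <- match.arg(direction)
  geo <- phantom_geometry(cfg)
  z <- geo$slice_z[[slice]]
  th <- (seq_len(n_sectors) - 0.5) * 2 * pi / n_sectors
  times <- (seq_len(cfg$n_frames) - 1) * cfg$tr
  peak <- analytic_peak_strains(cfg, geo, z, d = 0.5)
  amp <- if (direction == "circumferential") peak$ecc else peak$err
  out <- matrix(0, n_sectors, length(times))
  for (j in seq_len(n_sectors)) {
    a <- activation(times, sector_delay(cfg, th[j]), geo$period, cfg$systole_ms)
    out[j, ] <- amp * a
  }
  out
}

#' Analytic ground truth for a phantom configuration
#'
#' Peak layer strains, twist/torsion, uniformity indices, volumes and mass,
#' all derived in closed form from the deformation model (and, for CURE/RURE,
#' from \code{\link{uniformity_index}} applied to the analytic sector
#' curves).
#'
#' @param cfg A \code{\link{phantom_config}}.
#' @return Object of class \code{phantom_truth}: a list with
#'   \code{strain} (data.frame layer x direction, \%), \code{peak_twist}
#'   (degrees per short-axis slice), \code{peak_torsion} (degrees/cm),
#'   \code{cure}, \code{rure}, \code{edv}, \code{esv} (uL), \code{ef} (\%),
#'   \code{mass} (mg).
#' @export
ground_truth <- function(cfg) {
  geo <- phantom_geometry(cfg)
  layers <- c(endo = 1 / 6, mid = 0.5, epi = 5 / 6)
  # strain truth: ecc depth profile is slice-independent; err averaged over
  # the three short-axis slices (it depends on the slice radii).
  ecc <- 100 * (peak_circ_stretch(cfg, layers) - 1)
  err <- rowMeans(sapply(short_axis_labels(), function(sl)
    analytic_peak_strains(cfg, geo, geo$slice_z[[sl]], layers)$err))
  ell <- rep(100 * (cfg$long_stretch - 1), 3)
  strain <- data.frame(layer = names(layers), ecc = ecc, err = err, ell = ell,
                       row.names = NULL)

  peak_twist <- vapply(short_axis_labels(), function(sl)
    peak_twist_at(cfg, geo, geo$slice_z[[sl]]), numeric(1))
  peak_torsion <- (cfg$twist_apex_peak - cfg$twist_base_peak) /
    (cfg$long_axis_length_ed / 10)

  # degenerate zero-strain configs have no defined uniformity index
  idx_or_na <- function(direction) {
    mean(vapply(short_axis_labels(), function(sl)
      tryCatch(uniformity_index(analytic_sector_curves(cfg, sl,
                                                       direction))$index,
               error = function(e) NA_real_), numeric(1)))
  }
  cure <- idx_or_na("circumferential")
  rure <- idx_or_na("radial")

  edv <- (2 / 3) * pi * geo$R_nb^2 * (geo$L - geo$ta)
  epi_vol <- (2 / 3) * pi * geo$R_eb^2 * geo$L
  mass <- 1.05 * (epi_vol - edv)
  # Cavity volume vs time under the in-plane (fixed-slice) convention:
  # endocardial surface radius scales by lambda_c(depth 0) per sector.
  times <- (seq_len(cfg$n_frames) - 1) * cfg$tr
  th <- (seq_len(72) - 0.5) * 2 * pi / 72
  lam0_pk <- peak_circ_stretch(cfg, 0)
  cav <- vapply(times, function(t) {
    a <- activation(t, sector_delay(cfg, th), geo$period, cfg$systole_ms)
    edv * mean((1 + (lam0_pk - 1) * a)^2)
  }, numeric(1))
  esv <- min(cav)
  structure(list(strain = strain, peak_twist = peak_twist,
                 peak_torsion = peak_torsion, cure = cure, rure = rure,
                 edv = edv, esv = esv, ef = 100 * (edv - esv) / edv,
                 mass = mass, es_frame = which.min(cav)),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("phantom ground truth\n")
  print(round(x$strain[, -1], 2))
  cat(sprintf("  peak torsion %.2f deg/cm; CURE %.4f RURE %.4f\n",
              x$peak_torsion, x$cure, x$rure))
  cat(sprintf("  EDV %.1f uL, ESV %.1f uL, EF %.1f%%, mass %.1f mg\n",
              x$edv, x$esv, x$ef, x$mass))
  invisible(x)
}

# ---- rendering --------------------------------------------------------------

# Invert the radial part of the map: given deformed radius r, activation a and
# reference annulus [re, rp], solve r = (1 + (lam_pk(R) - 1) a) R for R.
# lam_pk is linear in R, so this is a quadratic with closed-form root.
#' @keywords internal
invert_radius <- function(cfg, r, a, re, rp) {
  W <- pmax(rp - re, 1e-12)
  Delta <- cfg$circ_stretch_epi - cfg$circ_stretch_endo
  beta <- 1.5 * Delta / W
  alpha <- cfg$circ_stretch_endo - 0.25 * Delta - beta * re
  A <- a * beta
  B <- 1 + a * (alpha - 1)
  R <- ifelse(abs(A) > 1e-14,
              (-B + sqrt(pmax(B^2 + 4 * A * r, 0))) / (2 * A),
              r / B)
  R
}

#' Render a synthetic cine DENSE study
#'
#' Generates the full five-slice study the acquisition protocol prescribes:
#' for every frame, each pixel inside the deformed myocardium receives the
#' displacement of the material point currently occupying it (relative to its
#' end-diastolic position), encoded into wrapped phase at the configured
#' encoding frequency, with optional seeded Gaussian phase noise; the
#' magnitude channel is a bright myocardium on a dark background.
#' End-diastolic contours are emitted exactly from the configured geometry.
#' Deterministic given the configuration (which includes the seed).
#'
#' @param cfg A \code{\link{phantom_config}}.
#' @return List with elements \code{study} (a \code{\link{dense_study}}) and
#'   \code{truth} (a \code{phantom_truth}, see \code{\link{ground_truth}}).
#' @export
render_study <- function(cfg) {
  if (cfg$n_frames < 2 || cfg$n_frames > 100)
    stop(sprintf("frame count %d outside [2, 100]; check heart_rate and tr",
                 cfg$n_frames))
  geo <- phantom_geometry(cfg)
  set.seed(cfg$random_seed)
  n <- cfg$matrix_size
  ps <- cfg$field_of_view / n
  times <- (seq_len(cfg$n_frames) - 1) * cfg$tr
  meta <- acquisition_meta(ke = cfg$ke, field_of_view = cfg$field_of_view,
                           matrix_size = n, tr = cfg$tr, frame_times = times)
  # pixel centre coordinates (x along columns, y along rows)
  coord <- (seq_len(n) - 0.5) * ps
  px <- matrix(coord, n, n, byrow = TRUE)   # x = column coordinate
  py <- matrix(coord, n, n)                 # y = row coordinate

  slices <- list()
  contours <- list()
  for (lab in short_axis_labels()) {
    z <- geo$slice_z[[lab]]
    rend <- render_sa_slice(cfg, geo, lab, z, px, py, times)
    slices[[lab]] <- dense_slice(lab, rend$mag, rend$phx, rend$phy, meta,
                                 slice_position = z)
    contours[[lab]] <- sa_contours(geo, z)
  }
  for (lab in c("two_chamber", "four_chamber")) {
    rend <- render_la_slice(cfg, geo, lab, px, py, times)
    slices[[lab]] <- dense_slice(lab, rend$mag, rend$phx, rend$phy, meta)
    contours[[lab]] <- la_contours(geo)
  }
  study <- dense_study(slices, contours,
                       subject_id = sprintf("phantom_seed%d", cfg$random_seed))
  list(study = study, truth = ground_truth(cfg))
}

#' @keywords internal
render_sa_slice <- function(cfg, geo, lab, z, px, py, times) {
  n <- nrow(px)
  re <- endo_radius_at(geo, z); rp <- epi_radius_at(geo, z)
  dims <- c(n, n, length(times))
  mag <- array(0, dims); phx <- array(0, dims); phy <- array(0, dims)
  dx <- px - geo$center[1]; dy <- py - geo$center[2]
  rho <- sqrt(dx^2 + dy^2)
  cand <- which(rho <= rp + 0.5)         # generous deformed-extent bound
  phi <- atan2(dy[cand], dx[cand])
  rhoc <- rho[cand]
  for (k in seq_along(times)) {
    t <- times[k]
    # fixed-point solve for the reference angle (delay and twist depend on it)
    Th <- phi
    for (it in 1:12) {
      a <- activation(t, sector_delay(cfg, Th), geo$period, cfg$systole_ms)
      Th <- phi - deg2rad(peak_twist_at(cfg, geo, z)) * a
    }
    a <- activation(t, sector_delay(cfg, Th), geo$period, cfg$systole_ms)
    R <- invert_radius(cfg, rhoc, a, re, rp)
    inside <- R >= re - 1e-9 & R <= rp + 1e-9
    idx <- cand[inside]
    # reference position via scaling and back-rotation of the pixel offset
    # vector itself (exactly the identity when the motion is zero)
    tw <- deg2rad(peak_twist_at(cfg, geo, z)) * a[inside]
    sc <- R[inside] / rhoc[inside]
    dxi <- dx[idx]; dyi <- dy[idx]
    refx <- geo$center[1] + sc * (cos(tw) * dxi + sin(tw) * dyi)
    refy <- geo$center[2] + sc * (-sin(tw) * dxi + cos(tw) * dyi)
    ux <- px[idx] - refx
    uy <- py[idx] - refy
    fx <- matrix(0, n, n); fy <- matrix(0, n, n); mg <- matrix(0, n, n)
    pxv <- 2 * pi * cfg$ke * ux
    pyv <- 2 * pi * cfg$ke * uy
    if (cfg$phase_noise_sd > 0) {
      pxv <- pxv + stats::rnorm(length(pxv), 0, cfg$phase_noise_sd)
      pyv <- pyv + stats::rnorm(length(pyv), 0, cfg$phase_noise_sd)
    }
    fx[idx] <- wrap_phase(pxv)
    fy[idx] <- wrap_phase(pyv)
    mg[idx] <- 1
    phx[, , k] <- fx; phy[, , k] <- fy; mag[, , k] <- mg
  }
  list(mag = mag, phx = phx, phy = phy)
}

#' @keywords internal
render_la_slice <- function(cfg, geo, lab, px, py, times) {
  n <- nrow(px)
  dims <- c(n, n, length(times))
  mag <- array(0, dims); phx <- array(0, dims); phy <- array(0, dims)
  h <- px - geo$la_origin[1]
  zz <- py - geo$la_origin[2]
  cand <- which(abs(h) <= geo$R_eb + 0.5 & zz >= -0.5 & zz <= geo$L + 0.5)
  hv <- h[cand]; zv <- zz[cand]
  theta_side <- la_side_angle(lab, hv)
  delay <- sector_delay(cfg, theta_side)
  for (k in seq_along(times)) {
    t <- times[k]
    a <- activation(t, delay, geo$period, cfg$systole_ms)
    lam_l <- 1 + (cfg$long_stretch - 1) * a
    Z <- zv / lam_l
    ok <- Z >= 0 & Z <= geo$L
    re <- endo_radius_at(geo, Z); rp <- epi_radius_at(geo, Z)
    R <- invert_radius(cfg, abs(hv), a, re, rp)
    inside <- ok & R >= re - 1e-9 & R <= rp + 1e-9 & rp > 1e-9
    idx <- cand[inside]
    ux <- hv[inside] - sign(hv[inside]) * R[inside]
    uy <- zv[inside] - Z[inside]
    pxv <- 2 * pi * cfg$ke * ux
    pyv <- 2 * pi * cfg$ke * uy
    if (cfg$phase_noise_sd > 0) {
      pxv <- pxv + stats::rnorm(length(pxv), 0, cfg$phase_noise_sd)
      pyv <- pyv + stats::rnorm(length(pyv), 0, cfg$phase_noise_sd)
    }
    fx <- matrix(0, n, n); fy <- matrix(0, n, n); mg <- matrix(0, n, n)
    fx[idx] <- wrap_phase(pxv)
    fy[idx] <- wrap_phase(pyv)
    mg[idx] <- 1
    phx[, , k] <- fx; phy[, , k] <- fy; mag[, , k] <- mg
  }
  list(mag = mag, phx = phx, phy = phy)
}

#' @keywords internal
sa_contours <- function(geo, z, n_vert = 72) {
  th <- (seq_len(n_vert) - 1) * 2 * pi / n_vert
  re <- endo_radius_at(geo, z); rp <- epi_radius_at(geo, z)
  contour_set(
    endocardium = cbind(geo$center[1] + re * cos(th), geo$center[2] + re * sin(th)),
    epicardium = cbind(geo$center[1] + rp * cos(th), geo$center[2] + rp * sin(th)))
}

#' @keywords internal
la_contours <- function(geo, n_side = 40) {
  sil <- function(rfun, z0) {
    zs <- seq(z0, geo$L, length.out = n_side)
    r <- rfun(zs)
    right <- cbind(r, zs)                       # apex -> base, +h side
    left <- cbind(-rev(r[-1]), rev(zs[-1]))     # base -> near-apex, -h side
    pts <- rbind(right, left)                   # apex vertex appears once
    cbind(geo$la_origin[1] + pts[, 1], geo$la_origin[2] + pts[, 2])
  }
  contour_set(
    endocardium = sil(function(z) endo_radius_at(geo, z), geo$ta),
    epicardium = sil(function(z) epi_radius_at(geo, z), 0))
}
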