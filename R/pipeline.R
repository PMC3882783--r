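# End-to-end study analysis: displacement decoding, tracking, strain by
# layer and segment, torsion, uniformity indices and volumetrics.

#' Analyse a cine DENSE study
#'
#' Runs the full pipeline on one study: per-slice phase unwrapping and
#' displacement decoding, motion-guided contour propagation, tissue
#' tracking, deformation-gradient strain estimation with layer and
#' 16-segment aggregation, longitudinal strain from the long-axis views,
#' slice twist and torsion, CURE/RURE uniformity indices, and EDV/ESV/EF/
#' mass from surface reconstruction.
#'
#' @param study A \code{\link{dense_study}}.
#' @param radius Strain-fit neighbourhood radius, mm (default 3 pixels).
#' @param order Local motion-model order for the deformation-gradient fit.
#' @param n_sectors Angular sectors per slice for the uniformity indices.
#' @param origin_angle_deg Segment/sector angular origin, degrees.
#' @param peak_per_segment If TRUE, layer peaks are the average of
#'   per-segment peaks; the default takes the peak of the segment-averaged
#'   curve.
#' @return Object of class \code{dense_analysis}; see Details.  The
#'   \code{metrics} element is a one-row data.frame of the scalar study
#'   metrics (peak strains by layer and direction in \%, peak torsion in
#'   degrees/cm, CURE, RURE, EDV/ESV in uL, EF in \%, mass in mg).
#' @export
analyze_study <- function(study, radius = NULL, order = 3L, n_sectors = 24L,
                          origin_angle_deg = -90, peak_per_segment = FALSE) {
  stopifnot(inherits(study, "dense_study"))
  sa <- short_axis_labels()

  fields <- lapply(study$slices, compute_displacement_field)
  seeds <- lapply(slice_labels(), function(lab)
    seed_mask(study$ed_contours[[lab]], fields[[lab]]))
  names(seeds) <- slice_labels()
  points <- lapply(slice_labels(), function(lab)
    track_points(fields[[lab]], seeds[[lab]]))
  names(points) <- slice_labels()

  samples <- list(); twist <- list(); propagated <- list()
  for (lab in sa) {
    samples[[lab]] <- strain_samples(points[[lab]], study$ed_contours[[lab]],
                                     lab, radius = radius, order = order)
    twist[[lab]] <- twist_angle(points[[lab]],
                                polygon_centroid(study$ed_contours[[lab]]$epicardium))
    propagated[[lab]] <- propagate_contours(study$ed_contours[[lab]],
                                            fields[[lab]])
  }

  seg_curves <- segment_layer_curves(samples)
  layer_peaks <- layer_peak_table(seg_curves, peak_per_segment)

  ell <- longitudinal_strain(points[["two_chamber"]],
                             study$ed_contours[["two_chamber"]],
                             points[["four_chamber"]],
                             study$ed_contours[["four_chamber"]],
                             radius = radius, order = order)
  ell_layer_peaks <- apply(ell$layer_curves, 1, peak_strain, "longitudinal")

  la_len <- vapply(c("two_chamber", "four_chamber"), function(lab) {
    p <- study$ed_contours[[lab]]$epicardium
    max(p[, 2]) - min(p[, 2])
  }, numeric(1))
  length_cm <- mean(la_len) / 10
  tors <- torsion(twist[["basal"]], twist[["apical"]], length_cm)

  syn <- list()
  for (dir in c("circumferential", "radial")) {
    idx <- vapply(sa, function(lab)
      uniformity_index(sector_curves(samples[[lab]], dir, n_sectors,
                                     origin_angle_deg))$index, numeric(1))
    syn[[dir]] <- list(per_slice = idx, average = mean(idx))
  }

  vol <- study_volumetry(study, propagated)

  metrics <- data.frame(
    ecc_endo = layer_peaks["endo", "ecc"], ecc_mid = layer_peaks["mid", "ecc"],
    ecc_epi = layer_peaks["epi", "ecc"],
    err_endo = layer_peaks["endo", "err"], err_mid = layer_peaks["mid", "err"],
    err_epi = layer_peaks["epi", "err"],
    ell_endo = ell_layer_peaks[["endo"]], ell_mid = ell_layer_peaks[["mid"]],
    ell_epi = ell_layer_peaks[["epi"]],
    ell_global = peak_strain(ell$curve, "longitudinal"),
    peak_torsion = tors$peak_torsion,
    cure = syn$circumferential$average, rure = syn$radial$average,
    edv_ul = vol$volumetry$edv, esv_ul = vol$volumetry$esv,
    ef_pct = vol$volumetry$ef, mass_mg = vol$volumetry$mass,
    mass_to_edv = vol$volumetry$mass_to_edv)

  structure(list(metrics = metrics, layer_peaks = layer_peaks,
                 segment_curves = seg_curves, samples = samples,
                 longitudinal = ell, twist = twist, torsion = tors,
                 synchrony = syn, volumetry = vol$volumetry,
                 es_frame = vol$es_frame, points = points,
                 propagated_contours = propagated,
                 subject_id = study$subject_id,
                 group_label = study$group_label),
            class = "dense_analysis")
}

# Myocardial seed mask: pixel centres between the end-diastolic contours
# that also carry signal in the frame-1 magnitude mask.
#' @keywords internal
seed_mask <- function(contours, field) {
  px <- field$px; py <- field$py
  m <- points_in_polygon(as.numeric(px), as.numeric(py), contours$epicardium) &
    !points_in_polygon(as.numeric(px), as.numeric(py), contours$endocardium)
  matrix(m, nrow(px), ncol(px)) & field$mask[[1]]
}

# Tidy per-segment, per-layer mean strain curves across the short-axis
# slices: slice, segment_id, layer, direction, frame, frame_time, strain.
#' @keywords internal
segment_layer_curves <- function(samples) {
  rows <- list()
  for (lab in names(samples)) {
    s <- samples[[lab]]
    for (dir in c("circumferential", "radial")) {
      col <- if (dir == "circumferential") "ecc" else "err"
      ok <- !is.na(s[[col]])
      agg <- stats::aggregate(s[[col]][ok],
                              by = list(segment_id = s$segment_id[ok],
                                        layer = s$layer[ok],
                                        frame = s$frame[ok],
                                        frame_time = s$frame_time[ok]),
                              FUN = mean)
      agg$slice <- lab
      agg$direction <- dir
      names(agg)[names(agg) == "x"] <- "strain"
      rows[[paste(lab, dir)]] <- agg
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$direction, out$segment_id, out$layer, out$frame), ]
}

# Layer peak table: average the per-segment curves within a layer (the
# 16-segment averaging), then take the curve's peak -- or average the
# per-segment peaks when peak_per_segment is TRUE.
#' @keywords internal
layer_peak_table <- function(seg_curves, peak_per_segment = FALSE) {
  layers <- c("endo", "mid", "epi")
  out <- matrix(NA_real_, 3, 2, dimnames = list(layers, c("ecc", "err")))
  for (dir in c("circumferential", "radial")) {
    col <- if (dir == "circumferential") "ecc" else "err"
    for (lay in layers) {
      sel <- seg_curves[seg_curves$direction == dir & seg_curves$layer == lay, ]
      if (!nrow(sel)) next
      if (peak_per_segment) {
        pk <- tapply(seq_len(nrow(sel)), sel$segment_id, function(ii)
          peak_strain(sel$strain[ii][order(sel$frame[ii])], dir))
        out[lay, col] <- mean(pk)
      } else {
        avg <- tapply(sel$strain, sel$frame, mean)
        out[lay, col] <- peak_strain(as.numeric(avg)[order(as.integer(names(avg)))],
                                     dir)
      }
    }
  }
  out
}

# ES frame selection and volumetrics from propagated contours.
#' @keywords internal
study_volumetry <- function(study, propagated) {
  sa <- c("apical", "mid", "basal")     # apical-to-basal order
  slice_z <- vapply(sa, function(lab) study$slices[[lab]]$slice_position,
                    numeric(1))
  la <- c("two_chamber", "four_chamber")
  epi_apex <- mean(vapply(la, function(lab)
    min(study$ed_contours[[lab]]$epicardium[, 2]), numeric(1)))
  epi_base <- mean(vapply(la, function(lab)
    max(study$ed_contours[[lab]]$epicardium[, 2]), numeric(1)))
  endo_apex <- mean(vapply(la, function(lab)
    min(study$ed_contours[[lab]]$endocardium[, 2]), numeric(1)))
  # convert image-vertical extents to heights above the epicardial apex
  base_z <- epi_base - epi_apex
  endo_apex_z <- endo_apex - epi_apex

  endo_at <- function(frame) {
    cons <- lapply(sa, function(lab) {
      cs <- if (frame == 1L) study$ed_contours[[lab]] else propagated[[lab]][[frame]]
      cs$endocardium
    })
    reconstruct_surface(cons, slice_z, apex_z = endo_apex_z, base_z = base_z)
  }
  endo_ed <- endo_at(1L)
  epi_ed <- reconstruct_surface(
    lapply(sa, function(lab) study$ed_contours[[lab]]$epicardium),
    slice_z, apex_z = 0, base_z = base_z)

  nfr <- length(propagated[["mid"]])
  cav <- vapply(seq_len(nfr), function(k) endo_at(k)$volume, numeric(1))
  es_frame <- which.min(cav)
  vol <- compute_volumetry(endo_ed, endo_at(es_frame), epi_ed)
  list(volumetry = vol, es_frame = es_frame, cavity_curve = cav)
}

#' @export
print.dense_analysis <- function(x, ...) {
  cat(sprintf("cine DENSE analysis of '%s'\n", x$subject_id))
  cat("peak layer strains (%):\n")
  print(round(x$layer_peaks, 2))
  cat(sprintf("longitudinal (global): %.2f%%\n", x$metrics$ell_global))
  cat(sprintf("peak torsion %.2f deg/cm; CURE %.4f, RURE %.4f\n",
              x$metrics$peak_torsion, x$metrics$cure, x$metrics$rure))
  print(x$volumetry)
  invisible(x)
}

#' @export
summary.dense_analysis <- function(object, ...) {
  df <- data.frame(metric = names(object$metrics),
                   value = as.numeric(object$metrics[1, ]))
  df$value <- round(df$value, 3)
  df
}

#' Export study metrics as JSON
#'
#' @param analysis A \code{\link{analyze_study}} result.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
export_metrics <- function(analysis, path) {
  stopifnot(inherits(analysis, "dense_analysis"))
  jsonlite::write_json(c(list(subject_id = analysis$subject_id),
                         as.list(analysis$metrics)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export per-segment strain curves as tidy CSV
#'
#' Columns: slice, segment_id, layer, direction, frame, frame_time_ms,
#' strain_percent.
#'
#' @param analysis A \code{\link{analyze_study}} result.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
export_strain_curves <- function(analysis, path) {
  stopifnot(inherits(analysis, "dense_analysis"))
  df <- analysis$segment_curves
  df <- df[, c("slice", "segment_id", "layer", "direction", "frame",
               "frame_time", "strain")]
  names(df)[6:7] <- c("frame_time_ms", "strain_percent")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
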