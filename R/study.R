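#' Acquisition metadata for a cine DENSE slice
#'
#' Bundles the acquisition parameters every downstream computation needs:
#' the displacement-encoding frequency \code{ke} (phase cycles accrued per mm
#' of tissue displacement, so displacement = phase / (2 pi ke)), the in-plane
#' pixel spacing, the repetition time, and the trigger-relative frame times.
#'
#' @param ke Displacement encoding frequency, cycles/mm. Must be positive.
#' @param field_of_view In-plane field of view, mm.
#' @param matrix_size Acquisition matrix size (square), pixels.
#' @param tr Repetition time, ms.
#' @param frame_times Numeric vector of frame times, ms from the R-wave
#'   trigger; strictly increasing, first element >= 0. Frame 1 is the
#'   end-diastolic reference (displacement zero).
#'
#' @return An object of class \code{acquisition_meta} with fields \code{ke},
#'   \code{pixel_spacing} (= field_of_view / matrix_size), \code{tr},
#'   \code{frame_times}, \code{field_of_view}, \code{matrix_size}.
#' @export
#' @examples
#' m <- acquisition_meta(ke = 1, field_of_view = 32, matrix_size = 128,
#'                       tr = 7.1, frame_times = seq(0, by = 7.1, length.out = 18))
#' m$pixel_spacing  # 0.25 mm
acquisition_meta <- function(ke, field_of_view, matrix_size, tr, frame_times) {
  stopifnot(is.numeric(ke), length(ke) == 1L)
  if (!is.finite(ke) || ke <= 0)
    stop("encoding frequency ke must be positive (cycles/mm)")
  if (!is.numeric(field_of_view) || field_of_view <= 0)
    stop("field_of_view must be positive (mm)")
  matrix_size <- as.integer(matrix_size)
  if (matrix_size <= 0) stop("matrix_size must be a positive integer")
  if (!is.numeric(tr) || tr <= 0) stop("repetition time tr must be positive (ms)")
  frame_times <- as.numeric(frame_times)
  if (length(frame_times) < 1L || frame_times[1] < 0 ||
      any(diff(frame_times) <= 0))
    stop("frame_times must be strictly increasing and start at >= 0")
  structure(list(
    ke = ke,
    pixel_spacing = field_of_view / matrix_size,
    tr = tr,
    frame_times = frame_times,
    field_of_view = field_of_view,
    matrix_size = matrix_size
  ), class = "acquisition_meta")
}

#' Warn if the encoding frequency is outside the protocol range
#'
#' The imaging protocol uses displacement encoding frequencies between 0.8 and
#' 1.0 cycles/mm; values outside that range are legal but flagged, since they
#' change the unambiguous displacement range (1 / (2 ke) mm) and the noise
#' behaviour of the decoded fields.
#'
#' @param meta An \code{\link{acquisition_meta}} object.
#' @return Character vector of warnings (zero length when \code{ke} lies in
#'   the closed interval [0.8, 1.0]). Never raises a condition.
#' @export
validate_encoding_range <- function(meta) {
  stopifnot(inherits(meta, "acquisition_meta"))
  if (meta$ke < 0.8 || meta$ke > 1.0) {
    sprintf("encoding frequency ke = %g cycles/mm outside protocol range [0.8, 1.0]",
            meta$ke)
  } else {
    character(0)
  }
}

#' One cine DENSE slice
#'
#' A slice holds the magnitude cine and the two wrapped displacement-phase
#' cines (x and y encoding), all as \code{nrow x ncol x nframes} arrays, plus
#' acquisition metadata and the slice position along the long axis.  Phase
#' values must lie in the half-open interval (-pi, pi].
#'
#' @param label One of \code{"basal"}, \code{"mid"}, \code{"apical"},
#'   \code{"two_chamber"}, \code{"four_chamber"}.
#' @param magnitude,phase_x,phase_y 3-D numeric arrays (row, col, frame).
#' @param meta An \code{\link{acquisition_meta}}.
#' @param slice_position For short-axis slices: height above the apex, mm.
#'   \code{NA} for long-axis slices.
#' @return Object of class \code{dense_slice}.
#' @export
dense_slice <- function(label, magnitude, phase_x, phase_y, meta,
                        slice_position = NA_real_) {
  label <- match.arg(label, slice_labels())
  stopifnot(inherits(meta, "acquisition_meta"))
  for (nm in c("magnitude", "phase_x", "phase_y")) {
    a <- get(nm)
    if (!is.array(a) || length(dim(a)) != 3L)
      stop(sprintf("%s must be a 3-D array (row, col, frame)", nm))
  }
  if (!identical(dim(magnitude), dim(phase_x)) ||
      !identical(dim(magnitude), dim(phase_y)))
    stop("magnitude, phase_x and phase_y must share identical dimensions")
  if (dim(magnitude)[3] != length(meta$frame_times))
    stop("frame count must match length(meta$frame_times)")
  for (nm in c("phase_x", "phase_y")) {
    a <- get(nm)
    if (any(a <= -pi - 1e-9) || any(a > pi + 1e-9))
      stop(sprintf("invariant violated: %s values must lie in (-pi, pi]", nm))
  }
  structure(list(
    label = label, magnitude = magnitude,
    phase_x = phase_x, phase_y = phase_y,
    meta = meta, slice_position = slice_position
  ), class = "dense_slice")
}

#' @keywords internal
slice_labels <- function() c("basal", "mid", "apical", "two_chamber", "four_chamber")

#' @keywords internal
short_axis_labels <- function() c("basal", "mid", "apical")

#' End-diastolic endo/epicardial contour pair
#'
#' @param endocardium,epicardium Closed planar polygons, n x 2 matrices of
#'   (x, y) vertex coordinates in mm (implicitly closed). The epicardium must
#'   enclose the endocardium and both must be simple (non self-intersecting).
#' @param frame_index 1-based frame the contours refer to (1 = end-diastole).
#' @return Object of class \code{contour_set}.
#' @export
contour_set <- function(endocardium, epicardium, frame_index = 1L) {
  endocardium <- as.matrix(endocardium)
  epicardium <- as.matrix(epicardium)
  stopifnot(ncol(endocardium) == 2L, ncol(epicardium) == 2L)
  if (!polygon_is_simple(endocardium))
    stop("invariant violated: endocardial polygon is self-intersecting")
  if (!polygon_is_simple(epicardium))
    stop("invariant violated: epicardial polygon is self-intersecting")
  # Enclosure checked on a slight inset of the endocardium so shared
  # boundary segments (e.g. an open base in long-axis silhouettes) pass.
  cen <- polygon_centroid(endocardium)
  ins <- 1 - 1e-6
  px <- cen[1] + ins * (endocardium[, 1] - cen[1])
  py <- cen[2] + ins * (endocardium[, 2] - cen[2])
  if (!all(points_in_polygon(px, py, epicardium)))
    stop("invariant violated: epicardium does not enclose endocardium")
  structure(list(endocardium = endocardium, epicardium = epicardium,
                 frame_index = as.integer(frame_index)),
            class = "contour_set")
}

#' A complete cine DENSE study
#'
#' The prescribed view set is three short-axis slices (basal, mid, apical)
#' and two long-axis slices (two- and four-chamber), each with end-diastolic
#' contours.  Frame 1 (the first frame after the R-wave trigger) is the
#' end-diastolic displacement reference.
#'
#' @param slices Named list of \code{\link{dense_slice}} objects covering the
#'   five prescribed views (names = labels).
#' @param ed_contours Named list of \code{\link{contour_set}} objects, one
#'   per slice, at the end-diastolic frame.
#' @param subject_id Character scalar.
#' @param group_label Optional character scalar (e.g. diet group).
#' @return Object of class \code{dense_study}.
#' @export
dense_study <- function(slices, ed_contours, subject_id = "subject",
                        group_label = NA_character_) {
  required <- slice_labels()
  missing <- setdiff(required, names(slices))
  if (length(missing))
    stop(sprintf("incomplete study: %s", paste(missing, collapse = ", ")))
  for (lab in required) {
    if (!inherits(slices[[lab]], "dense_slice"))
      stop(sprintf("slices[['%s']] is not a dense_slice", lab))
    if (slices[[lab]]$label != lab)
      stop(sprintf("slice stored under '%s' is labelled '%s'", lab,
                   slices[[lab]]$label))
  }
  missing_c <- setdiff(required, names(ed_contours))
  if (length(missing_c))
    stop(sprintf("incomplete study: missing contours for %s",
                 paste(missing_c, collapse = ", ")))
  for (lab in required)
    stopifnot(inherits(ed_contours[[lab]], "contour_set"))
  structure(list(slices = slices[required], ed_contours = ed_contours[required],
                 subject_id = as.character(subject_id),
                 group_label = as.character(group_label)),
            class = "dense_study")
}

#' @export
print.dense_study <- function(x, ...) {
  s1 <- x$slices[[1]]
  cat(sprintf("cine DENSE study '%s'%s\n", x$subject_id,
              if (!is.na(x$group_label)) sprintf(" [%s]", x$group_label) else ""))
  cat(sprintf("  5 slices (%s), %d frames, %d x %d matrix\n",
              paste(names(x$slices), collapse = ", "),
              dim(s1$magnitude)[3], dim(s1$magnitude)[1], dim(s1$magnitude)[2]))
  cat(sprintf("  ke = %g cycles/mm, pixel %g mm, TR %g ms\n",
              s1$meta$ke, s1$meta$pixel_spacing, s1$meta$tr))
  invisible(x)
}
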