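# On-disk study container: one NIfTI volume per channel per slice
# (<label>_mag.nii, <label>_phx.nii, <label>_phy.nii), a study.json sidecar
# holding acquisition metadata and slice positions, and contours.json with
# per-slice end-diastolic endo/epi vertex lists in mm.  Serialization order is
# fixed (label order, field order, full-precision doubles) so two writes of
# the same study produce byte-identical sidecars.

#' Write a cine DENSE study to a directory
#'
#' @param study A \code{\link{dense_study}}.
#' @param path Directory to create/fill.
#' @return Invisibly, \code{path}.
#' @seealso \code{\link{read_study}}
#' @export
write_study <- function(study, path) {
  stopifnot(inherits(study, "dense_study"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop(sprintf("cannot create directory '%s'", path))

  meta_list <- list()
  for (lab in slice_labels()) {
    sl <- study$slices[[lab]]
    RNifti::writeNifti(RNifti::asNifti(sl$magnitude, datatype = "double"),
                       file.path(path, paste0(lab, "_mag.nii")))
    RNifti::writeNifti(RNifti::asNifti(sl$phase_x, datatype = "double"),
                       file.path(path, paste0(lab, "_phx.nii")))
    RNifti::writeNifti(RNifti::asNifti(sl$phase_y, datatype = "double"),
                       file.path(path, paste0(lab, "_phy.nii")))
    meta_list[[lab]] <- list(
      label = lab,
      ke = sl$meta$ke,
      field_of_view = sl$meta$field_of_view,
      matrix_size = sl$meta$matrix_size,
      tr = sl$meta$tr,
      frame_times = sl$meta$frame_times,
      slice_position = if (is.na(sl$slice_position)) NULL else sl$slice_position
    )
  }
  sidecar <- list(subject_id = study$subject_id,
                  group_label = if (is.na(study$group_label)) NULL else study$group_label,
                  slices = meta_list)
  jsonlite::write_json(sidecar, file.path(path, "study.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  contours <- lapply(study$ed_contours[slice_labels()], function(cs) {
    list(frame_index = cs$frame_index,
         endocardium = unname(apply(cs$endocardium, 1, as.numeric, simplify = FALSE)),
         epicardium = unname(apply(cs$epicardium, 1, as.numeric, simplify = FALSE)))
  })
  jsonlite::write_json(contours, file.path(path, "contours.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Read a cine DENSE study from a directory
#'
#' Loads a directory written by \code{\link{write_study}} and re-validates
#' every type invariant (five views present, matching stack dimensions, phase
#' in (-pi, pi], simple nested contours).
#'
#' @param path Directory containing the study container.
#' @return A validated \code{\link{dense_study}}.
#' @export
read_study <- function(path) {
  sidecar_path <- file.path(path, "study.json")
  if (!file.exists(sidecar_path))
    stop(sprintf("no study.json sidecar in '%s'", path))
  sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  missing <- setdiff(slice_labels(), names(sidecar$slices))
  if (length(missing))
    stop(sprintf("incomplete study: %s", paste(missing, collapse = ", ")))

  slices <- list()
  for (lab in slice_labels()) {
    for (ch in c("mag", "phx", "phy")) {
      f <- file.path(path, paste0(lab, "_", ch, ".nii"))
      if (!file.exists(f))
        stop(sprintf("incomplete study: %s (missing %s volume)", lab, ch))
    }
    sm <- sidecar$slices[[lab]]
    meta <- acquisition_meta(ke = sm$ke, field_of_view = sm$field_of_view,
                             matrix_size = sm$matrix_size, tr = sm$tr,
                             frame_times = unlist(sm$frame_times))
    rd <- function(ch) {
      a <- RNifti::readNifti(file.path(path, paste0(lab, "_", ch, ".nii")))
      array(as.numeric(a), dim = dim(a))
    }
    slices[[lab]] <- dense_slice(
      label = lab, magnitude = rd("mag"), phase_x = rd("phx"),
      phase_y = rd("phy"), meta = meta,
      slice_position = if (is.null(sm$slice_position)) NA_real_ else sm$slice_position)
  }

  cj <- jsonlite::read_json(file.path(path, "contours.json"),
                            simplifyVector = TRUE, simplifyDataFrame = FALSE)
  contours <- list()
  for (lab in slice_labels()) {
    cc <- cj[[lab]]
    if (is.null(cc)) stop(sprintf("incomplete study: missing contours for %s", lab))
    tomat <- function(v) {
      if (is.matrix(v)) v else do.call(rbind, lapply(v, unlist))
    }
    contours[[lab]] <- contour_set(tomat(cc$endocardium), tomat(cc$epicardium),
                                   frame_index = cc$frame_index)
  }
  dense_study(slices, contours,
              subject_id = sidecar$subject_id,
              group_label = if (is.null(sidecar$group_label)) NA_character_
                            else sidecar$group_label)
}
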