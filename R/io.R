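#' Read fiducial-marker tracks from CSV
#'
#' The interchange format is a CSV with header
#' `patient_id,phase_label,marker_id,lr_mm,ap_mm,si_mm` and one row per
#' (phase, marker) pair.  Every marker must have exactly one position at
#' every phase of `phases`; gaps are reported by name.
#'
#' @param path Path to the CSV file.
#' @param phases A [phase_set()] the tracks must cover.
#' @param patient_id Optional: if given, keep only this patient's rows.
#' @return Named list of n_phases-by-3 track matrices (mm), suitable for
#'   [four_d_study()].
#' @export
read_marker_tracks <- function(path, phases, patient_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("patient_id", "phase_label", "marker_id",
            "lr_mm", "ap_mm", "si_mm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("marker track file '", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!is.null(patient_id)) {
    df <- df[df$patient_id == patient_id, , drop = FALSE]
    if (nrow(df) == 0L)
      stop("no rows for patient '", patient_id, "' in '", path, "'")
  } else if (length(unique(df$patient_id)) > 1L) {
    stop("file '", path, "' holds several patients (",
         paste(unique(df$patient_id), collapse = ", "),
         "); pass patient_id to select one")
  }
  for (col in c("lr_mm", "ap_mm", "si_mm")) {
    val <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(val) & nzchar(df[[col]]))
    if (length(bad) || anyNA(val))
      stop("non-numeric ", col, " in '", path, "' at data row ",
           paste(utils::head(c(bad, which(is.na(val))), 1), collapse = ", "))
    df[[col]] <- val
  }
  ids <- sort(unique(df$marker_id))
  key <- paste(df$phase_label, df$marker_id, sep = "\r")
  tracks <- lapply(ids, function(id) {
    m <- matrix(NA_real_, n_phases(phases), 3L,
                dimnames = list(phases$labels, c("lr_mm", "ap_mm", "si_mm")))
    for (pi in seq_along(phases$labels)) {
      row <- which(key == paste(phases$labels[pi], id, sep = "\r"))
      if (length(row) == 0L)
        stop("marker track file '", path, "' is missing (marker '", id,
             "', phase '", phases$labels[pi], "')")
      if (length(row) > 1L)
        stop("duplicate rows for (marker '", id, "', phase '",
             phases$labels[pi], "') in '", path, "'")
      m[pi, ] <- c(df$lr_mm[row], df$ap_mm[row], df$si_mm[row])
    }
    m
  })
  names(tracks) <- ids
  tracks
}

#' Write fiducial-marker tracks to CSV
#'
#' Inverse of [read_marker_tracks()]: coordinates are written with full
#' precision (`format(..., digits = 17)`) so a round trip is exact.
#'
#' @param tracks Named list of track matrices (see [four_d_study()]).
#' @param phases The [phase_set()] the rows follow.
#' @param patient_id Patient identifier written to every row.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_marker_tracks <- function(tracks, phases, patient_id, path) {
  rows <- do.call(rbind, lapply(names(tracks), function(id) {
    m <- tracks[[id]]
    data.frame(patient_id = patient_id, phase_label = phases$labels,
               marker_id = id,
               lr_mm = format(m[, 1], digits = 17, trim = TRUE,
                              scientific = FALSE),
               ap_mm = format(m[, 2], digits = 17, trim = TRUE,
                              scientific = FALSE),
               si_mm = format(m[, 3], digits = 17, trim = TRUE,
                              scientific = FALSE),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-phase binary mask from a NIfTI volume
#'
#' Any nonzero voxel is taken as occupied.  Voxel spacing comes from the
#' NIfTI `pixdim`; the origin (center of the first voxel) from the
#' translation column of the stored transform.  File axes are mapped onto
#' the patient axes (LR, AP, SI) by `axis_mapping`, declared explicitly
#' rather than inferred from orientation codes: per-direction results make
#' a silent axis permutation the most dangerous failure mode, so the
#' mapping is part of the study manifest.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param axis_mapping Integer permutation of 1:3 mapping file axes to
#'   (LR, AP, SI); the default is the identity.
#' @return A [voxel_mask()].
#' @export
read_phase_mask <- function(path, axis_mapping = 1:3) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("'", path, "' is not a 3-D volume (dims: ",
         paste(dim(img), collapse = "x"), ")")
  spacing <- RNifti::pixdim(img)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'", path, "' lacks valid voxel spacing metadata")
  origin <- RNifti::xform(img)[1:3, 4]
  occ <- as.array(img) != 0
  axis_mapping <- check_axis_mapping(axis_mapping)
  if (!identical(axis_mapping, 1:3)) {
    occ <- aperm(occ, order(axis_mapping))
    spacing <- spacing[order(axis_mapping)]
    origin <- origin[order(axis_mapping)]
  }
  voxel_mask(occ, spacing = spacing, origin = origin)
}

check_axis_mapping <- function(axis_mapping) {
  axis_mapping <- as.integer(axis_mapping)
  if (!identical(sort(axis_mapping), 1:3))
    stop("axis_mapping must be a permutation of 1:3")
  axis_mapping
}

#' Write a binary mask as a NIfTI volume
#'
#' @param mask A [voxel_mask()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_phase_mask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask$occupancy),
                               dim = dim(mask$occupancy)))
  RNifti::pixdim(img) <- mask$spacing
  m <- diag(4)
  m[1, 1] <- mask$spacing[1]
  m[2, 2] <- mask$spacing[2]
  m[3, 3] <- mask$spacing[3]
  m[1:3, 4] <- mask$origin
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a complete 4D study to disk
#'
#' Writes one NIfTI mask per phase (`{patient}_phase{label}.nii.gz`), a
#' marker-track CSV, and a YAML manifest tying them together.
#'
#' @param study A [four_d_study()].
#' @param dir Output directory (created if needed).
#' @return Path of the manifest file, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pid <- study$patient_id
  safe_labels <- gsub("%", "", study$phases$labels)
  mask_files <- sprintf("%s_phase%s.nii.gz", pid, safe_labels)
  for (i in seq_along(study$gtv_masks))
    write_phase_mask(study$gtv_masks[[i]], file.path(dir, mask_files[i]))
  track_file <- sprintf("%s_markers.csv", pid)
  write_marker_tracks(study$markers, study$phases, pid,
                      file.path(dir, track_file))
  manifest <- list(patient_id = pid,
                   phase_labels = as.list(study$phases$labels),
                   reference_phase = reference_label(study$phases),
                   mask_files = as.list(mask_files),
                   track_file = track_file,
                   axis_mapping = as.list(1:3))
  manifest_path <- file.path(dir, sprintf("%s_manifest.yaml", pid))
  yaml::write_yaml(manifest, manifest_path)
  invisible(manifest_path)
}

#' Read a 4D study from a manifest written by [write_study()]
#'
#' @param manifest_path Path to the YAML manifest.
#' @return A [four_d_study()].
#' @export
read_study <- function(manifest_path) {
  man <- yaml::read_yaml(manifest_path)
  need <- c("patient_id", "phase_labels", "reference_phase",
            "mask_files", "track_file")
  missing_keys <- setdiff(need, names(man))
  if (length(missing_keys))
    stop("manifest '", manifest_path, "' lacks key(s): ",
         paste(missing_keys, collapse = ", "))
  phases <- phase_set(unlist(man$phase_labels), man$reference_phase)
  dir <- dirname(manifest_path)
  axis_mapping <- if (is.null(man$axis_mapping)) 1:3 else
    unlist(man$axis_mapping)
  masks <- lapply(unlist(man$mask_files), function(f)
    read_phase_mask(file.path(dir, f), axis_mapping = axis_mapping))
  tracks <- read_marker_tracks(file.path(dir, man$track_file), phases,
                               patient_id = man$patient_id)
  four_d_study(man$patient_id, phases, masks, tracks)
}
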