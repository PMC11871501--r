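#' One patient's 4D study: per-phase GTV masks plus marker tracks
#'
#' The unit of analysis.  Holds one binary GTV mask per respiratory phase
#' (all on a single shared grid) and the per-phase 3-D coordinates of at
#' least two fiducial markers.
#'
#' Marker tracks are stored as a named list of numeric matrices, one matrix
#' per marker, with one row per phase (ordered as in `phases`) and columns
#' `lr_mm`, `ap_mm`, `si_mm`.  Only the marker *centroid* coordinates are
#' stored; physical marker size plays no role in the computation.
#'
#' @param patient_id Character scalar identifier.
#' @param phases A [phase_set()].
#' @param gtv_masks List of [voxel_mask()] objects, one per phase, all on
#'   one grid, each non-empty.
#' @param markers Named list (>= 2 elements) of n_phases-by-3 numeric
#'   matrices of marker coordinates in mm.
#' @return An object of class `four_d_study`.
#' @export
four_d_study <- function(patient_id, phases, gtv_masks, markers) {
  stopifnot(inherits(phases, "phase_set"))
  patient_id <- as.character(patient_id)
  if (length(patient_id) != 1L || !nzchar(patient_id))
    stop("patient_id must be a non-empty string")
  np <- n_phases(phases)
  if (length(gtv_masks) != np)
    stop("study '", patient_id, "': expected ", np, " GTV masks, got ",
         length(gtv_masks))
  for (m in gtv_masks) {
    if (!inherits(m, "voxel_mask")) stop("gtv_masks must be voxel_mask objects")
    if (!same_grid(m, gtv_masks[[1]]))
      stop("study '", patient_id, "': all GTV masks must share one grid")
    if (!any(m$occupancy))
      stop("study '", patient_id, "': empty GTV mask encountered")
  }
  markers <- validate_marker_tracks(markers, np, patient_id)
  structure(list(patient_id = patient_id, phases = phases,
                 gtv_masks = gtv_masks, markers = markers),
            class = "four_d_study")
}

validate_marker_tracks <- function(markers, np, patient_id = "?") {
  if (length(markers) < 2L)
    stop("study '", patient_id, "': at least 2 markers required, got ",
         length(markers))
  ids <- names(markers)
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids))
    stop("markers must be a named list with distinct non-empty ids")
  out <- lapply(ids, function(id) {
    m <- as.matrix(markers[[id]])
    storage.mode(m) <- "double"
    if (nrow(m) != np || ncol(m) != 3L)
      stop("study '", patient_id, "', marker '", id, "': track must be ",
           np, "x3, got ", nrow(m), "x", ncol(m))
    if (any(!is.finite(m)))
      stop("study '", patient_id, "', marker '", id,
           "': non-finite coordinate")
    colnames(m) <- c("lr_mm", "ap_mm", "si_mm")
    m
  })
  names(out) <- ids
  out
}

#' @rdname four_d_study
#' @param study A `four_d_study`.
#' @return `marker_ids()`: character vector of marker identifiers.
#' @export
marker_ids <- function(study) names(study$markers)

#' GTV centroids of every phase
#'
#' @param study A `four_d_study`.
#' @return n_phases-by-3 matrix of GTV centroids (mm), rows in phase order.
#' @export
gtv_centroids <- function(study) {
  ctr <- t(vapply(study$gtv_masks, mask_centroid, numeric(3)))
  dimnames(ctr) <- list(study$phases$labels, c("lr_mm", "ap_mm", "si_mm"))
  ctr
}

#' @export
print.four_d_study <- function(x, ...) {
  cat("<four_d_study> '", x$patient_id, "': ", n_phases(x$phases),
      " phases (reference ", reference_label(x$phases), "), ",
      length(x$markers), " markers [",
      paste(marker_ids(x), collapse = ", "), "]\n", sep = "")
  cat("  grid: ", paste(mask_shape(x$gtv_masks[[1]]), collapse = "x"),
      " voxels @ (", paste(format(x$gtv_masks[[1]]$spacing), collapse = ", "),
      ") mm\n", sep = "")
  invisible(x)
}
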