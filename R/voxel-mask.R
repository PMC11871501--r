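#' Binary voxel mask on a regular mm grid
#'
#' Raster representation of a delineated structure (e.g. a GTV) on a patient
#' coordinate grid.  Axes are patient axes in millimetres, in the fixed order
#' left-right (LR), anterior-posterior (AP), superior-inferior (SI).  The
#' `origin` is the physical coordinate of the *center* of voxel index
#' (1,1,1); voxel (i,j,k) is centered at `origin + (c(i,j,k) - 1) * spacing`
#' (center-of-voxel semantics, as in NIfTI).
#'
#' @param occupancy Logical (or coercible) 3-D array; `TRUE` marks occupied
#'   voxels.
#' @param spacing Numeric length-3 vector of voxel sizes in mm, all > 0.
#' @param origin Numeric length-3 vector, mm coordinate of the first voxel
#'   center.
#' @return An object of class `voxel_mask`.
#' @seealso [mask_centroid()], [mask_volume()], [shift_mask()],
#'   [expand_mask()], [union_masks()]
#' @export
voxel_mask <- function(occupancy, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(occupancy)) != 3L)
    stop("occupancy must be a 3-D array, got ",
         length(dim(occupancy)), " dimension(s)")
  storage.mode(occupancy) <- "logical"
  if (anyNA(occupancy)) stop("occupancy contains NA")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 finite positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values (mm)")
  structure(list(occupancy = occupancy, spacing = spacing, origin = origin),
            class = "voxel_mask")
}

#' @rdname voxel_mask
#' @param mask A `voxel_mask`.
#' @return `mask_shape()`: integer length-3 voxel counts.
#' @export
mask_shape <- function(mask) dim(mask$occupancy)

#' Occupied volume of a mask
#'
#' @param mask A `voxel_mask`.
#' @return Volume in mm^3: occupied-voxel count times the voxel volume.
#' @export
mask_volume <- function(mask) sum(mask$occupancy) * prod(mask$spacing)

#' Centroid of a voxel mask
#'
#' Unweighted mean of the occupied voxel center coordinates, in mm, on the
#' (LR, AP, SI) patient axes.  This is the substrate for every GTV-centroid
#' quantity in the TLE analysis.
#'
#' @param mask A `voxel_mask` with at least one occupied voxel.
#' @return Named numeric length-3 vector `(lr_mm, ap_mm, si_mm)`.
#' @export
mask_centroid <- function(mask) {
  idx <- which(mask$occupancy, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty: centroid undefined")
  ctr <- mask$origin + (colMeans(idx) - 1) * mask$spacing
  names(ctr) <- c("lr_mm", "ap_mm", "si_mm")
  ctr
}

#' Grid compatibility check
#'
#' Two masks are on the same grid when origin, spacing and shape agree to
#' within `tol` (mm for origin/spacing).
#' @param a,b `voxel_mask` objects.
#' @param tol Numeric tolerance in mm.
#' @return Logical scalar.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$occupancy), dim(b$occupancy)) &&
    all(abs(a$origin - b$origin) < tol) &&
    all(abs(a$spacing - b$spacing) < tol)
}

#' Pad a mask with empty voxels on all sides
#'
#' Extends the grid by at least `pad_mm` of physical distance per side on
#' each axis (rounded up to whole voxels), keeping the occupied voxels at
#' the same physical coordinates.  Used before shifting or expanding masks
#' so structures cannot fall off the grid.
#'
#' @param mask A `voxel_mask`.
#' @param pad_mm Numeric length-1 or length-3, padding per side in mm.
#' @return A padded `voxel_mask` covering the original.
#' @export
pad_mask <- function(mask, pad_mm) {
  pad_mm <- rep_len(as.numeric(pad_mm), 3L)
  if (any(pad_mm < 0)) stop("pad_mm must be non-negative")
  nvox <- as.integer(ceiling(pad_mm / mask$spacing))
  if (all(nvox == 0L)) return(mask)
  old <- dim(mask$occupancy)
  occ <- array(FALSE, dim = old + 2L * nvox)
  occ[nvox[1] + seq_len(old[1]),
      nvox[2] + seq_len(old[2]),
      nvox[3] + seq_len(old[3])] <- mask$occupancy
  voxel_mask(occ, spacing = mask$spacing,
             origin = mask$origin - nvox * mask$spacing)
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat("<voxel_mask> ", paste(dim(x$occupancy), collapse = "x"),
      " voxels, spacing (", paste(format(x$spacing), collapse = ", "),
      ") mm, ", sum(x$occupancy), " occupied (",
      format(mask_volume(x)), " mm^3)\n", sep = "")
  invisible(x)
}
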