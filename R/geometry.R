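round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# translate a logical array by integer voxel offsets; clip = TRUE drops
# voxels pushed past the edge, clip = FALSE errors on them
shift_array <- function(occ, off, clip = FALSE) {
  d <- dim(occ)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    s <- seq_len(d[a])
    keep <- s + off[a] >= 1L & s + off[a] <= d[a]
    if (!clip && !all(keep)) {
      lost <- occ
      # any occupied voxel outside the kept source range falls off-grid
      idx <- which(!keep)
      sub <- switch(a,
                    occ[idx, , , drop = FALSE],
                    occ[, idx, , drop = FALSE],
                    occ[, , idx, drop = FALSE])
      if (any(sub))
        stop("shift pushes occupied voxels off the grid on axis ", a,
             "; pad the grid first (see pad_mask)")
    }
    src[[a]] <- s[keep]
    dst[[a]] <- s[keep] + off[a]
  }
  out <- array(FALSE, dim = d)
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    occ[src[[1]], src[[2]], src[[3]], drop = FALSE]
  out
}

#' Translate a mask by a physical shift, snapped to whole voxels
#'
#' The shift is converted to voxels per axis and rounded
#' half-away-from-zero to the nearest whole-voxel offset; binary occupancy
#' is then index-shifted, so volume is conserved exactly and no
#' interpolation pseudo-volume appears.  The applied offset and the
#' sub-voxel remainder (mm) are recorded as attributes `"offset_voxels"`
#' and `"remainder_mm"` of the result; the snapping error is at most half
#' a voxel per axis.
#'
#' @param mask A [voxel_mask()].
#' @param shift Numeric length-3 shift in mm (LR, AP, SI).
#' @return The shifted [voxel_mask()] on the same grid.  Errors if an
#'   occupied voxel would leave the grid.
#' @export
shift_mask <- function(mask, shift) {
  shift <- as.numeric(shift)
  if (length(shift) != 3L || any(!is.finite(shift)))
    stop("shift must be 3 finite values (mm)")
  off <- as.integer(round_half_away(shift / mask$spacing))
  out <- voxel_mask(shift_array(mask$occupancy, off),
                    spacing = mask$spacing, origin = mask$origin)
  attr(out, "offset_voxels") <- off
  attr(out, "remainder_mm") <- shift - off * mask$spacing
  out
}

#' Voxelwise union of masks on a shared grid
#'
#' @param masks List of [voxel_mask()] objects on one grid.
#' @return A [voxel_mask()] occupied wherever any input is occupied.
#' @export
union_masks <- function(masks) {
  if (length(masks) == 0L) stop("no masks to union")
  for (m in masks[-1])
    if (!same_grid(m, masks[[1]]))
      stop("union_masks requires all masks on one grid")
  occ <- Reduce(`|`, lapply(masks, `[[`, "occupancy"))
  voxel_mask(occ, spacing = masks[[1]]$spacing, origin = masks[[1]]$origin)
}

#' Union of marker-aligned per-phase GTVs
#'
#' For each phase p the GTV mask is translated by the alignment shift
#' `s_p = M_ref - M_p` of the chosen marker combination, then all phases
#' (the reference one unshifted) are unioned.  This is the target that
#' compensates residual tumor-marker asynchrony under marker-centroid
#' tracking.  The grid is padded by the largest shift beforehand so no
#' phase falls off.
#'
#' @param study A [four_d_study()].
#' @param combination Marker ids to align on (default: all markers).
#' @param extra_pad_mm Additional padding in mm kept around the union
#'   (useful when the result will be compared against expanded targets on
#'   the same grid).
#' @return A [voxel_mask()] on the padded grid.
#' @export
build_gtv_union_shift <- function(study, combination = marker_ids(study),
                                  extra_pad_mm = 0) {
  shifts <- t(vapply(seq_len(n_phases(study$phases)),
                     function(p) alignment_shift(study, combination, p),
                     numeric(3)))
  pad <- apply(abs(shifts), 2, max) + study$gtv_masks[[1]]$spacing +
    extra_pad_mm
  shifted <- lapply(seq_len(nrow(shifts)), function(p)
    shift_mask(pad_mask(study$gtv_masks[[p]], pad), shifts[p, ]))
  union_masks(shifted)
}

# integer voxel offsets inside the ellipsoid with mm semi-axes `margins`
ellipsoid_offsets <- function(margins, spacing) {
  rng <- lapply(1:3, function(a) {
    if (margins[a] == 0) 0L else seq(-floor(margins[a] / spacing[a]),
                                     floor(margins[a] / spacing[a]))
  })
  grid <- expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]])
  d <- rep(0, nrow(grid))
  for (a in 1:3) {
    if (margins[a] > 0)
      d <- d + (grid[[a]] * spacing[a] / margins[a])^2
  }
  grid[d <= 1 + 1e-12, , drop = FALSE]
}

#' Anisotropic margin expansion of a mask
#'
#' Morphological dilation with an ellipsoidal structuring element of mm
#' semi-axes `(lr, ap, si)`: a voxel becomes occupied iff its center lies
#' within the axis-scaled distance
#' `sqrt(sum((delta_axis / margin_axis)^2)) <= 1` of some occupied voxel
#' center.  An axis with margin 0 admits no displacement on that axis;
#' all-zero margins give the identity.  Expansion is clipped at the grid
#' boundary - pad first (see [pad_mask()]) if the margin must be honoured
#' near the edge.
#'
#' @param mask A [voxel_mask()].
#' @param margins Numeric length-3 non-negative margins in mm (LR, AP,
#'   SI); a scalar is recycled (isotropic margin).
#' @return The expanded [voxel_mask()] on the same grid (a superset of
#'   the input).
#' @export
expand_mask <- function(mask, margins) {
  margins <- rep_len(as.numeric(margins), 3L)
  if (any(!is.finite(margins)) || any(margins < 0))
    stop("margins must be finite and >= 0 (mm)")
  if (all(margins == 0)) return(mask)
  offs <- ellipsoid_offsets(margins, mask$spacing)
  occ <- mask$occupancy
  out <- occ
  for (r in seq_len(nrow(offs))) {
    off <- c(offs$i[r], offs$j[r], offs$k[r])
    if (all(off == 0L)) next
    out <- out | shift_array(occ, off, clip = TRUE)
  }
  voxel_mask(out, spacing = mask$spacing, origin = mask$origin)
}

#' Build the target set for one study
#'
#' Assembles, on one padded grid:
#' * `gtv_ref` - the reference-phase GTV;
#' * `gtv_union_shift` - the union of marker-aligned per-phase GTVs;
#' * `gtv_tle_ref` - `gtv_ref` expanded anisotropically by the TLE
#'   margins;
#' * `ptv_tle_ref` - `gtv_tle_ref` expanded isotropically by the PTV
#'   margin (default 5 mm).
#'
#' The clinical target volume is taken as identical to the GTV, so no
#' separate CTV mask exists.  The grid is padded by the largest alignment
#' shift plus both margins so every construction stays on-grid.
#'
#' @param study A [four_d_study()].
#' @param tle_margin Numeric length-3 (LR, AP, SI) TLE margin in mm,
#'   e.g. from [tle_margins()].
#' @param ptv_margin_mm Isotropic PTV margin in mm (default 5).
#' @param combination Marker ids used for alignment (default: all).
#' @return An object of class `target_set` with the four masks and the
#'   margins used.
#' @export
make_target_set <- function(study, tle_margin, ptv_margin_mm = 5,
                            combination = marker_ids(study)) {
  tle_margin <- rep_len(as.numeric(tle_margin), 3L)
  if (any(tle_margin < 0) || ptv_margin_mm < 0)
    stop("margins must be >= 0")
  spacing <- study$gtv_masks[[1]]$spacing
  pad <- max(tle_margin) + ptv_margin_mm + spacing
  union <- build_gtv_union_shift(study, combination, extra_pad_mm = pad)
  ref <- pad_to_grid(study$gtv_masks[[study$phases$reference_index]], union)
  gtv_tle_ref <- expand_mask(ref, tle_margin)
  ptv_tle_ref <- expand_mask(gtv_tle_ref, rep(ptv_margin_mm, 3L))
  structure(list(gtv_ref = ref, gtv_union_shift = union,
                 gtv_tle_ref = gtv_tle_ref, ptv_tle_ref = ptv_tle_ref,
                 tle_margin = tle_margin, ptv_margin_mm = ptv_margin_mm,
                 combination = combination,
                 patient_id = study$patient_id),
            class = "target_set")
}

# embed `mask` into the (larger, aligned) grid of `template`
pad_to_grid <- function(mask, template) {
  off <- (mask$origin - template$origin) / mask$spacing
  offi <- as.integer(round(off))
  if (any(abs(off - offi) > 1e-6))
    stop("grids are not voxel-aligned; cannot embed")
  d <- dim(mask$occupancy)
  D <- dim(template$occupancy)
  if (any(offi < 0L) || any(offi + d > D))
    stop("mask does not fit inside the template grid")
  occ <- array(FALSE, dim = D)
  occ[offi[1] + seq_len(d[1]), offi[2] + seq_len(d[2]),
      offi[3] + seq_len(d[3])] <- mask$occupancy
  voxel_mask(occ, spacing = template$spacing, origin = template$origin)
}

#' Geometric comparison of the TLE-margin target against the union target
#'
#' Computes the three validation metrics:
#' * `r_v_union_ref` - volume ratio of `gtv_tle_ref` to
#'   `gtv_union_shift`;
#' * `centroid_distance_mm` - 3-D Euclidean distance between the two
#'   centroids;
#' * `coverage_fraction_geometric` - the fraction of the union target's
#'   volume contained in `ptv_tle_ref`.  This is a purely geometric
#'   containment measure: a conformal plan prescribes full dose to the
#'   PTV, so voxels of the union target outside the PTV are the ones at
#'   risk of underdose.
#'
#' @param ts A `target_set` from [make_target_set()].
#' @return A one-row data.frame with the metrics plus the structure
#'   volumes in cm^3.
#' @export
compare_targets <- function(ts) {
  stopifnot(inherits(ts, "target_set"))
  v_union <- mask_volume(ts$gtv_union_shift)
  if (v_union == 0) stop("gtv_union_shift is empty")
  v_tle <- mask_volume(ts$gtv_tle_ref)
  c_union <- mask_centroid(ts$gtv_union_shift)
  c_tle <- mask_centroid(ts$gtv_tle_ref)
  inter <- sum(ts$gtv_union_shift$occupancy & ts$ptv_tle_ref$occupancy)
  data.frame(patient_id = ts$patient_id,
             volume_union_cm3 = v_union / 1000,
             volume_tle_ref_cm3 = v_tle / 1000,
             r_v_union_ref = v_tle / v_union,
             centroid_distance_mm = sqrt(sum((c_tle - c_union)^2)),
             coverage_fraction_geometric =
               inter / sum(ts$gtv_union_shift$occupancy),
             stringsAsFactors = FALSE)
}
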