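#' Enumerate marker combinations
#'
#' All subsets of the given marker ids with at least `min_size` members,
#' in deterministic order: by subset size, then lexicographically by the
#' sorted member ids.  A 5-marker case yields choose(5,2) = 10 two-marker
#' subsets and 26 subsets in total at the default minimum of 2.
#'
#' @param ids Character vector of distinct marker ids.
#' @param min_size Smallest subset size (default 2; single markers are
#'   never used by default).
#' @return List of character vectors, each a sorted marker-id subset.
#' @export
enumerate_combinations <- function(ids, min_size = 2L) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("marker ids must be distinct")
  if (length(ids) < min_size)
    stop("need at least ", min_size, " markers, got ", length(ids))
  ids <- sort(ids)
  out <- list()
  for (k in seq(min_size, length(ids))) {
    subsets <- utils::combn(ids, k, simplify = FALSE)
    keys <- vapply(subsets, paste, "", collapse = "\r")
    out <- c(out, subsets[order(keys)])
  }
  out
}

#' Centroid of a marker combination at one phase
#'
#' Unweighted mean of the member markers' positions at the given phase.
#'
#' @param study A [four_d_study()].
#' @param combination Character vector of marker ids in the study.
#' @param phase Phase index (1-based) or phase label.
#' @return Named numeric length-3 position (mm).
#' @export
combination_centroid <- function(study, combination, phase) {
  track <- combination_track(study, combination)
  p <- resolve_phase(study$phases, phase)
  ctr <- track[p, ]
  names(ctr) <- c("lr_mm", "ap_mm", "si_mm")
  ctr
}

resolve_phase <- function(phases, phase) {
  if (is.character(phase)) {
    p <- match(phase, phases$labels)
    if (is.na(p)) stop("unknown phase label '", phase, "'")
    return(p)
  }
  p <- as.integer(phase)
  if (p < 1L || p > n_phases(phases)) stop("phase index out of range: ", p)
  p
}

# n_phases x 3 trajectory of a combination's marker centroid
combination_track <- function(study, combination) {
  combination <- as.character(combination)
  missing_ids <- setdiff(combination, marker_ids(study))
  if (length(missing_ids))
    stop("study '", study$patient_id, "' has no marker(s): ",
         paste(missing_ids, collapse = ", "))
  if (anyDuplicated(combination)) stop("combination ids must be distinct")
  Reduce(`+`, study$markers[combination]) / length(combination)
}

#' Alignment shift of one phase onto the reference phase
#'
#' The translation `s_p = M_ref - M_p` that moves phase-p structures so the
#' phase-p marker centroid `M_p` lands on the reference-phase marker
#' centroid `M_ref`.  By construction the reference phase's shift is zero.
#'
#' @inheritParams combination_centroid
#' @return Named numeric length-3 shift (mm).
#' @export
alignment_shift <- function(study, combination, phase) {
  track <- combination_track(study, combination)
  p <- resolve_phase(study$phases, phase)
  s <- track[study$phases$reference_index, ] - track[p, ]
  names(s) <- c("lr_mm", "ap_mm", "si_mm")
  s
}

#' Per-direction RMSE of the aligned GTV centroid for one combination
#'
#' After aligning every phase on the combination's marker centroid, the
#' GTV centroid of phase p sits at `G_p + s_p`; its deviation from the
#' reference GTV centroid is the localization residual.  Per axis,
#' `RMSE = sqrt(mean over non-reference phases of residual^2)`, with the
#' N in the mean equal to the number of non-reference phases (9 for a
#' 10-phase study).
#'
#' The default `"centroid"` method uses the algebraically identical
#' shortcut `(G_p - M_p) - (G_ref - M_ref)`: translating a rigid mask
#' moves its centroid by exactly the shift, so no mask is touched.  The
#' `"mask"` method actually shifts each phase's mask (voxel-snapped, see
#' [shift_mask()]) and recomputes centroids; it agrees with the shortcut
#' to within the sub-voxel snapping remainder and exists for end-to-end
#' validation.
#'
#' @param study A [four_d_study()].
#' @param combination Character vector of marker ids.
#' @param method `"centroid"` (exact shortcut) or `"mask"` (shift masks).
#' @return Named numeric length-3 RMSE (mm) per direction (LR, AP, SI).
#' @export
rmse_per_direction <- function(study, combination,
                               method = c("centroid", "mask")) {
  method <- match.arg(method)
  ref <- study$phases$reference_index
  np <- n_phases(study$phases)
  if (method == "centroid") {
    g <- gtv_centroids(study)
    m <- combination_track(study, combination)
    res <- sweep(g - m, 2, g[ref, ] - m[ref, ])
  } else {
    g_ref <- mask_centroid(study$gtv_masks[[ref]])
    res <- t(vapply(seq_len(np), function(p) {
      s <- alignment_shift(study, combination, p)
      need <- pmax(0, abs(s)) + study$gtv_masks[[p]]$spacing
      shifted <- shift_mask(pad_mask(study$gtv_masks[[p]], need), s)
      mask_centroid(shifted) - g_ref
    }, numeric(3)))
  }
  rmse <- sqrt(colMeans(res[-ref, , drop = FALSE]^2))
  names(rmse) <- c("lr_mm", "ap_mm", "si_mm")
  rmse
}

#' Evaluate every marker combination of one or more studies
#'
#' Runs [rmse_per_direction()] for every subset from
#' [enumerate_combinations()] of every study, together with the two
#' combination-level covariates used in the correlation analysis:
#' the per-direction marker-GTV distance at the reference phase and the
#' per-direction respiratory motion of the combination centroid.
#'
#' @param studies A [four_d_study()] or list of them.
#' @param min_size Smallest combination size (default 2).
#' @param method RMSE evaluation mode, see [rmse_per_direction()].
#' @param motion Respiratory-motion convention, see
#'   [respiratory_marker_motion()].
#' @return A data.frame with one row per (study, combination):
#'   `patient_id`, `marker_ids` ("+"-joined), `k`, `rmse_lr/ap/si`,
#'   `dist_lr/ap/si`, `dist_3d`, `motion_lr/ap/si`.
#' @export
compute_combination_results <- function(studies, min_size = 2L,
                                        method = "centroid",
                                        motion = "from_reference") {
  if (inherits(studies, "four_d_study")) studies <- list(studies)
  rows <- lapply(studies, function(study) {
    combos <- enumerate_combinations(marker_ids(study), min_size = min_size)
    do.call(rbind, lapply(combos, function(cmb) {
      rmse <- rmse_per_direction(study, cmb, method = method)
      dist <- marker_gtv_distance(study, cmb)
      mot <- respiratory_marker_motion(study, cmb, mode = motion)
      data.frame(patient_id = study$patient_id,
                 marker_ids = paste(cmb, collapse = "+"),
                 k = length(cmb),
                 rmse_lr = rmse[1], rmse_ap = rmse[2], rmse_si = rmse[3],
                 dist_lr = dist["lr_mm"], dist_ap = dist["ap_mm"],
                 dist_si = dist["si_mm"], dist_3d = dist["euclidean_mm"],
                 motion_lr = mot[1], motion_ap = mot[2], motion_si = mot[3],
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pool combination RMSEs into a TLE report
#'
#' Groups combination-level RMSE values by marker count k (rows "Two",
#' "Three", "Four", "Five", pooled across patients) plus an "All" row, and
#' reports per group and direction the RMSE range, its standard deviation,
#' and the 95th percentile, which is defined as the target localization
#' error (TLE).
#'
#' The percentile uses linear interpolation between closest order
#' statistics (rank `h = p * (n - 1)`, zero-based; `stats::quantile`
#' type 7), so pooled values 1..20 give a P95 of 19.05.  The SD divisor is
#' the population one (n) by default.  Both conventions are exposed.
#'
#' @param results Data.frame from [compute_combination_results()].
#' @param prob Percentile defining the TLE (default 0.95).
#' @param quantile_type Order-statistic interpolation, passed to
#'   [stats::quantile()] (default 7 = linear interpolation).
#' @param sd_divisor `"n"` (population, default) or `"n-1"` (sample).
#' @return A data.frame of class `tle_report`: columns `group`, `k`, `n`,
#'   `direction`, `rmse_min`, `rmse_max`, `rmse_sd`, `tle`.
#' @export
pool_tle <- function(results, prob = 0.95, quantile_type = 7L,
                     sd_divisor = c("n", "n-1")) {
  sd_divisor <- match.arg(sd_divisor)
  if (nrow(results) == 0L) stop("no combination results to pool")
  group_names <- c(`2` = "Two", `3` = "Three", `4` = "Four", `5` = "Five")
  ks <- sort(unique(results$k))
  groups <- c(lapply(ks, function(k) {
    list(label = if (as.character(k) %in% names(group_names))
      group_names[[as.character(k)]] else as.character(k),
      k = k, rows = results[results$k == k, , drop = FALSE])
  }), list(list(label = "All", k = NA_integer_, rows = results)))
  dir_cols <- c(LR = "rmse_lr", AP = "rmse_ap", SI = "rmse_si")
  out <- do.call(rbind, lapply(groups, function(g) {
    do.call(rbind, lapply(names(dir_cols), function(d) {
      x <- g$rows[[dir_cols[[d]]]]
      sdv <- if (sd_divisor == "n")
        sqrt(mean((x - mean(x))^2)) else stats::sd(x)
      data.frame(group = g$label, k = g$k, n = length(x), direction = d,
                 rmse_min = min(x), rmse_max = max(x), rmse_sd = sdv,
                 tle = unname(stats::quantile(x, prob,
                                              type = quantile_type)),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  class(out) <- c("tle_report", "data.frame")
  out
}

#' Extract per-axis TLE margins from a report
#'
#' @param report A `tle_report` from [pool_tle()].
#' @param group Group row to read (default `"All"`: the TLE pooled over
#'   every combination of every patient).
#' @return Named numeric length-3 margin (mm) in (LR, AP, SI) order.
#' @export
tle_margins <- function(report, group = "All") {
  rows <- report[report$group == group, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no group '", group, "' in report")
  m <- rows$tle[match(c("LR", "AP", "SI"), rows$direction)]
  names(m) <- c("lr_mm", "ap_mm", "si_mm")
  m
}
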