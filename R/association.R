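#' Marker-GTV distance of a combination at the reference phase
#'
#' Per-direction absolute distance between the combination's marker
#' centroid and the GTV centroid, both taken at the reference phase, plus
#' the 3-D Euclidean distance.  One of the two covariates examined for
#' association with the localization error.
#'
#' @param study A [four_d_study()].
#' @param combination Character vector of marker ids.
#' @return Named numeric vector `(lr_mm, ap_mm, si_mm, euclidean_mm)`.
#' @export
marker_gtv_distance <- function(study, combination) {
  ref <- study$phases$reference_index
  m <- combination_centroid(study, combination, ref)
  g <- mask_centroid(study$gtv_masks[[ref]])
  d <- abs(m - g)
  c(d, euclidean_mm = sqrt(sum((m - g)^2)))
}

#' Respiratory motion of a combination's marker centroid
#'
#' Per-direction motion magnitude of the marker-subset centroid across the
#' respiratory cycle.  The default convention is the maximum absolute
#' displacement from the reference phase; `"peak_to_peak"` reports the
#' max-minus-min excursion over all phases instead.  The second covariate
#' of the association analysis.
#'
#' @param study A [four_d_study()].
#' @param combination Character vector of marker ids.
#' @param mode `"from_reference"` (default) or `"peak_to_peak"`.
#' @return Named numeric length-3 motion (mm) per direction.
#' @export
respiratory_marker_motion <- function(study, combination,
                                      mode = c("from_reference",
                                               "peak_to_peak")) {
  mode <- match.arg(mode)
  track <- combination_track(study, combination)
  out <- if (mode == "from_reference") {
    ref <- study$phases$reference_index
    apply(abs(sweep(track, 2, track[ref, ])), 2, max)
  } else {
    apply(track, 2, max) - apply(track, 2, min)
  }
  names(out) <- c("lr_mm", "ap_mm", "si_mm")
  out
}

#' Correlate combination-level RMSE with its covariates
#'
#' Pearson correlation of the per-combination RMSE against the
#' marker-GTV distance and the respiratory marker motion, per direction,
#' within each marker-count group and over all combinations pooled.
#'
#' The localization error enters per combination (the group-level TLE is a
#' single percentile and admits no correlation), with the covariates taken
#' for the combination's marker centroid.  Two-sided p-values come from
#' the exact t transform with n - 2 degrees of freedom
#' ([stats::cor.test()]).  Groups with fewer than `min_n` combinations, or
#' with zero variance in either variable, are skipped with a warning.
#'
#' @param results Data.frame from [compute_combination_results()].
#' @param min_n Smallest group size correlated (default 3).
#' @return Data.frame: `group`, `direction`, `covariate`, `n`,
#'   `pearson_r`, `p_value`.
#' @export
correlate_tle <- function(results, min_n = 3L) {
  group_names <- c(`2` = "Two", `3` = "Three", `4` = "Four", `5` = "Five")
  groups <- c(lapply(sort(unique(results$k)), function(k)
    list(label = group_names[[as.character(k)]],
         rows = results[results$k == k, , drop = FALSE])),
    list(list(label = "All", rows = results)))
  covs <- c(marker_gtv_distance = "dist", respiratory_marker_motion = "motion")
  dirs <- c(LR = "lr", AP = "ap", SI = "si")
  out <- list()
  for (g in groups) for (d in names(dirs)) for (cv in names(covs)) {
    x <- g$rows[[paste0(covs[[cv]], "_", dirs[[d]])]]
    y <- g$rows[[paste0("rmse_", dirs[[d]])]]
    if (length(x) < min_n) {
      warning("group '", g$label, "' has fewer than ", min_n,
              " combinations; skipped", call. = FALSE)
      next
    }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("zero variance in group '", g$label, "', direction ", d,
              ", covariate ", cv, "; skipped", call. = FALSE)
      next
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    out[[length(out) + 1L]] <-
      data.frame(group = g$label, direction = d, covariate = cv,
                 n = length(x), pearson_r = unname(ct$estimate),
                 p_value = ct$p.value, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) stop("no group admitted a correlation")
  do.call(rbind, out)
}
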