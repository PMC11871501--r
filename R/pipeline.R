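#' Run the TLE stage over a cohort
#'
#' Evaluates every marker combination of every study and pools the
#' per-direction RMSEs into the grouped TLE report (marker-count groups
#' Two..Five plus All).
#'
#' @param studies List of [four_d_study()] objects (or one study).
#' @param min_size Smallest combination size (default 2).
#' @param ... Passed on to [pool_tle()] (percentile and SD conventions).
#' @return List with `combinations` (the per-combination table) and
#'   `report` (the `tle_report`).
#' @export
run_tle_stage <- function(studies, min_size = 2L, ...) {
  combos <- compute_combination_results(studies, min_size = min_size)
  list(combinations = combos, report = pool_tle(combos, ...))
}

#' Run the margin-validation stage over a cohort
#'
#' For each study, builds the union-of-aligned-GTVs target and the
#' TLE-margin reference target (plus its PTV), and tabulates the geometric
#' comparison metrics.  Rows with `coverage_fraction_geometric < 1` are
#' flagged in `under_covered`: part of the union target falls outside the
#' PTV, i.e. the margins do not absorb that study's asynchrony.
#'
#' @param studies List of [four_d_study()] objects.
#' @param tle_margin Length-3 (LR, AP, SI) margin in mm, typically the
#'   cohort-level "All" TLE from [tle_margins()]; a per-study list is also
#'   accepted.
#' @param ptv_margin_mm Isotropic PTV margin in mm (default 5).
#' @return Data.frame with one row per study: volumes, `r_v_union_ref`,
#'   `centroid_distance_mm`, `coverage_fraction_geometric`,
#'   `under_covered`.
#' @export
run_validation_stage <- function(studies, tle_margin, ptv_margin_mm = 5) {
  if (inherits(studies, "four_d_study")) studies <- list(studies)
  per_study <- !is.numeric(tle_margin)
  rows <- lapply(seq_along(studies), function(i) {
    margin <- if (per_study) tle_margin[[i]] else tle_margin
    ts <- make_target_set(studies[[i]], margin, ptv_margin_mm)
    compare_targets(ts)
  })
  out <- do.call(rbind, rows)
  out$under_covered <- out$coverage_fraction_geometric < 1
  rownames(out) <- NULL
  out
}

#' Write a TLE report to CSV and JSON
#'
#' The CSV mirrors the grouped report layout (group, n, direction, RMSE
#' range, SD, TLE) with mm values rounded to one decimal for display; the
#' JSON keeps full precision and round-trips through
#' [read_tle_report_json()].
#'
#' @param report A `tle_report` from [pool_tle()].
#' @param path_csv,path_json Output paths; either may be `NULL` to skip.
#' @return Invisibly, the written paths.
#' @export
write_tle_report <- function(report, path_csv = NULL, path_json = NULL) {
  stopifnot(inherits(report, "tle_report"))
  order_idx <- order(match(report$group,
                           c("Two", "Three", "Four", "Five", "All")),
                     match(report$direction, c("LR", "AP", "SI")))
  report <- report[order_idx, , drop = FALSE]
  if (!is.null(path_csv)) {
    disp <- report
    for (col in c("rmse_min", "rmse_max", "rmse_sd", "tle"))
      disp[[col]] <- sprintf("%.1f", disp[[col]])
    utils::write.csv(disp, path_csv, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(path_json))
    jsonlite::write_json(as.data.frame(report), path_json, digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
  invisible(c(csv = path_csv, json = path_json))
}

#' @rdname write_tle_report
#' @param path Path of a JSON report written by [write_tle_report()].
#' @export
read_tle_report_json <- function(path) {
  out <- jsonlite::fromJSON(path)
  out$k <- as.integer(out$k)
  class(out) <- c("tle_report", "data.frame")
  out
}

#' @export
print.tle_report <- function(x, ...) {
  cat("TLE report (TLE = 95th percentile of per-combination RMSE, mm)\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}
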