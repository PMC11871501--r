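#' Draw a random phantom specification for one synthetic patient
#'
#' Samples plausible lung-SBRT motion parameters: dominant
#' superior-inferior tumor excursion (5-15 mm peak), smaller
#' anterior-posterior (1-5 mm) and left-right (0.5-3 mm) components, and
#' markers whose trajectories differ from the tumor's by per-marker phase
#' lags (up to `max_lag` cycles) and per-axis amplitude mismatches (within
#' `amplitude_jitter` of the tumor's) - the tumor-marker asynchrony the TLE
#' quantifies.  Marker rest positions sit 10-30 mm from the tumor in random
#' directions.  Positional noise (`noise_sd`, default 0.3 mm per axis)
#' stands in for delineation and localization jitter.
#'
#' All draws happen under a local RNG seeded by `seed`, which also seeds
#' the phantom build, so `(n_markers, seed)` fully determines the study.
#'
#' @param n_markers Number of fiducial markers (2-5).
#' @param seed Integer seed.
#' @param spacing Grid spacing in mm (default 1 mm isotropic in-plane with
#'   a 2.5 mm slice, the coarser of the scanner setups emulated).
#' @param waveform Trajectory waveform, see [motion_config()].
#' @param noise_sd Positional noise SD in mm applied to tumor and markers.
#' @param max_lag Largest per-marker phase lag in cycles.
#' @param amplitude_jitter Half-width of the per-axis marker amplitude
#'   scale factor around 1.
#' @param tumor_radius_range_mm Range the tumor radius is drawn from.
#' @return A [phantom_spec()].
#' @export
random_phantom_spec <- function(n_markers, seed, spacing = c(1, 1, 2.5),
                                waveform = "cos4", noise_sd = 0.3,
                                max_lag = 0.1, amplitude_jitter = 0.15,
                                tumor_radius_range_mm = c(5, 12)) {
  if (n_markers < 2L) stop("n_markers must be >= 2")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  amp <- c(stats::runif(1, 0.5, 3),   # LR
           stats::runif(1, 1, 5),     # AP
           stats::runif(1, 5, 15))    # SI
  radius <- stats::runif(1, tumor_radius_range_mm[1],
                         tumor_radius_range_mm[2])
  tumor <- motion_config(amplitude = amp, phase_lag = 0,
                         baseline = c(0, 0, 0), noise_sd = noise_sd,
                         waveform = waveform)
  markers <- lapply(seq_len(n_markers), function(i) {
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    motion_config(
      amplitude = amp * stats::runif(3, 1 - amplitude_jitter,
                                     1 + amplitude_jitter),
      phase_lag = stats::runif(1, -max_lag, max_lag),
      baseline = dir * stats::runif(1, 10, 30),
      noise_sd = noise_sd, waveform = waveform)
  })
  names(markers) <- sprintf("m%d", seq_len(n_markers))
  phantom_spec(tumor, markers, tumor_radius_mm = radius, spacing = spacing,
               seed = seed, grid_pad_mm = 5 + 4 * noise_sd)
}

#' Simulate a cohort of synthetic 4D studies
#'
#' One phantom per entry of `marker_counts`, each drawn by
#' [random_phantom_spec()] under a seed derived deterministically from
#' `seed` and the patient index.
#'
#' The default `marker_counts` reproduce the marker-count distribution of
#' the TLE-evaluation cohort: 11 patients with 2/3/4/5 markers in
#' proportions 1/2/4/4.  `validation_marker_counts()` gives the 10-patient
#' validation distribution (2/5/3/0).
#'
#' @param seed Integer master seed.
#' @param marker_counts Integer vector, one entry (2-5) per patient.
#' @param ... Passed to [random_phantom_spec()].
#' @return Named list of [four_d_study()] objects (`P01`, `P02`, ...).
#' @export
simulate_cohort <- function(seed, marker_counts = tle_marker_counts(), ...) {
  studies <- lapply(seq_along(marker_counts), function(i) {
    spec <- random_phantom_spec(marker_counts[i], seed = seed * 1009L + i,
                                ...)
    build_phantom(spec, patient_id = sprintf("P%02d", i))
  })
  names(studies) <- vapply(studies, `[[`, "", "patient_id")
  studies
}

#' @rdname simulate_cohort
#' @export
tle_marker_counts <- function() c(2L, 3L, 3L, 4L, 4L, 4L, 4L, 5L, 5L, 5L, 5L)

#' @rdname simulate_cohort
#' @export
validation_marker_counts <- function() c(2L, 2L, 3L, 3L, 3L, 3L, 3L, 4L, 4L, 4L)
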