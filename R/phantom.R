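#' Periodic motion model for one object (tumor or marker)
#'
#' Describes the respiratory trajectory of one rigid object as
#' `baseline + amplitude * w(t_p + phase_lag) + drift_per_phase * p + noise`,
#' with `t_p = p / n_phases` for phase index `p = 0, ..., n_phases - 1`.
#' Asynchrony between tumor and markers is injected through per-object
#' phase lags and amplitude differences: this is exactly the quantity the
#' TLE analysis measures.
#'
#' Waveforms: `"sinusoid"` is `sin(2*pi*t)` and admits closed-form oracles;
#' `"cos4"` is the Lujan-style `cos(pi*t)^4` that dwells at exhale, closer
#' to real breathing.
#'
#' @param amplitude Per-axis peak displacement in mm, length 1 or 3
#'   (LR, AP, SI); all >= 0.
#' @param phase_lag Fractional cycle offset (cycles).
#' @param baseline Rest position in mm, length 3.
#' @param drift_per_phase Linear drift in mm per phase index, length 1 or 3.
#' @param noise_sd Positional noise SD in mm, length 1 or 3; >= 0.
#' @param waveform `"sinusoid"` or `"cos4"`.
#' @return An object of class `motion_config`.
#' @export
motion_config <- function(amplitude = c(0, 0, 0), phase_lag = 0,
                          baseline = c(0, 0, 0),
                          drift_per_phase = c(0, 0, 0),
                          noise_sd = 0, waveform = "sinusoid") {
  amplitude <- rep_len(as.numeric(amplitude), 3L)
  drift_per_phase <- rep_len(as.numeric(drift_per_phase), 3L)
  noise_sd <- rep_len(as.numeric(noise_sd), 3L)
  baseline <- as.numeric(baseline)
  if (length(baseline) != 3L) stop("baseline must have 3 components")
  if (any(amplitude < 0)) stop("amplitudes must be >= 0")
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0")
  waveform <- match.arg(waveform, c("sinusoid", "cos4"))
  structure(list(amplitude = amplitude, phase_lag = as.numeric(phase_lag),
                 baseline = baseline, drift_per_phase = drift_per_phase,
                 noise_sd = noise_sd, waveform = waveform),
            class = "motion_config")
}

waveform_value <- function(waveform, t) {
  switch(waveform,
         sinusoid = sin(2 * pi * t),
         cos4 = cos(pi * t)^4,
         stop("unknown waveform '", waveform, "'"))
}

#' Simulate one object's per-phase trajectory
#'
#' Evaluates the [motion_config()] model at the discrete phase times
#' `t_p = p / n` (`p = 0..n-1`), adding iid Gaussian noise per axis when
#' `noise_sd > 0`.  Noise is drawn from the current RNG state; pass `seed`
#' to fix it locally (the caller's RNG state is restored on exit).
#'
#' @param config A [motion_config()].
#' @param phases A [phase_set()].
#' @param seed Optional integer seed for the noise draws.
#' @return n_phases-by-3 matrix of positions in mm (LR, AP, SI).
#' @export
simulate_trajectory <- function(config, phases, seed = NULL) {
  stopifnot(inherits(config, "motion_config"), inherits(phases, "phase_set"))
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  np <- n_phases(phases)
  p <- seq_len(np) - 1
  t_p <- p / np
  w <- waveform_value(config$waveform, t_p + config$phase_lag)
  pos <- outer(w, config$amplitude) +
    outer(p, config$drift_per_phase) +
    matrix(config$baseline, np, 3L, byrow = TRUE)
  if (any(config$noise_sd > 0))
    pos <- pos + matrix(stats::rnorm(3L * np, sd = rep(config$noise_sd,
                                                       each = np)), np, 3L)
  dimnames(pos) <- list(phases$labels, c("lr_mm", "ap_mm", "si_mm"))
  pos
}

#' Specification of a synthetic 4D respiratory phantom
#'
#' A spherical tumor and point fiducial markers, each with its own
#' [motion_config()], rasterized on a mm voxel grid.  When `grid_origin` /
#' `grid_shape` are `NULL` the grid is auto-fitted to the noise-free tumor
#' trajectory plus radius plus `grid_pad_mm` per side (noise can still push
#' the sphere off an auto-fitted grid if `grid_pad_mm` is small relative to
#' `noise_sd`).
#'
#' @param tumor [motion_config()] of the tumor center.
#' @param markers Named list (>= 2) of [motion_config()] objects.
#' @param tumor_radius_mm Sphere radius in mm (> 0).
#' @param spacing Voxel spacing in mm, length 1 or 3.
#' @param phases A [phase_set()].
#' @param seed Integer seed fixing all randomness of [build_phantom()].
#' @param grid_origin,grid_shape Optional explicit grid.
#' @param grid_pad_mm Padding per side for the auto-fitted grid.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(tumor, markers, tumor_radius_mm = 10,
                         spacing = c(1, 1, 2.5), phases = phase_set(),
                         seed = 1L, grid_origin = NULL, grid_shape = NULL,
                         grid_pad_mm = 5) {
  stopifnot(inherits(tumor, "motion_config"))
  if (length(markers) < 2L || is.null(names(markers)))
    stop("markers must be a named list of >= 2 motion_config objects")
  for (m in markers) stopifnot(inherits(m, "motion_config"))
  if (tumor_radius_mm <= 0) stop("tumor_radius_mm must be > 0")
  structure(list(tumor = tumor, markers = markers,
                 tumor_radius_mm = as.numeric(tumor_radius_mm),
                 spacing = rep_len(as.numeric(spacing), 3L),
                 phases = phases, seed = as.integer(seed),
                 grid_origin = grid_origin, grid_shape = grid_shape,
                 grid_pad_mm = as.numeric(grid_pad_mm)),
            class = "phantom_spec")
}

noise_free_trajectory <- function(config, phases) {
  cfg <- config
  cfg$noise_sd <- c(0, 0, 0)
  simulate_trajectory(cfg, phases)
}

phantom_grid <- function(spec) {
  if (!is.null(spec$grid_origin) && !is.null(spec$grid_shape))
    return(list(origin = as.numeric(spec$grid_origin),
                shape = as.integer(spec$grid_shape)))
  traj <- noise_free_trajectory(spec$tumor, spec$phases)
  lo <- apply(traj, 2, min) - spec$tumor_radius_mm - spec$grid_pad_mm
  hi <- apply(traj, 2, max) + spec$tumor_radius_mm + spec$grid_pad_mm
  shape <- as.integer(ceiling((hi - lo) / spec$spacing)) + 1L
  list(origin = lo, shape = shape)
}

#' Rasterize a sphere on a voxel grid
#'
#' A voxel is occupied iff its center lies within `radius` of `center`.
#'
#' @param center Sphere center, mm (LR, AP, SI).
#' @param radius Radius in mm.
#' @param origin,spacing,shape Grid geometry as in [voxel_mask()].
#' @return A [voxel_mask()].
#' @export
rasterize_sphere <- function(center, radius, origin, spacing, shape) {
  ax <- lapply(1:3, function(a)
    (origin[a] + (seq_len(shape[a]) - 1) * spacing[a] - center[a])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  voxel_mask(d2 <= radius^2, spacing = spacing, origin = origin)
}

#' Build a synthetic 4D study from a phantom specification
#'
#' Simulates the tumor and marker trajectories (all randomness is fixed by
#' `spec$seed`), rasterizes the tumor sphere at every phase, and assembles
#' a [four_d_study()].  Errors if the sphere leaves the grid at any phase.
#'
#' @param spec A [phantom_spec()].
#' @param patient_id Identifier for the resulting study.
#' @return A [four_d_study()].
#' @export
build_phantom <- function(spec, patient_id = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- phantom_grid(spec)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  tumor_pos <- simulate_trajectory(spec$tumor, spec$phases)
  tracks <- lapply(spec$markers, simulate_trajectory, phases = spec$phases)
  grid_hi <- grid$origin + (grid$shape - 1) * spec$spacing
  masks <- lapply(seq_len(n_phases(spec$phases)), function(p) {
    ctr <- tumor_pos[p, ]
    if (any(ctr - spec$tumor_radius_mm < grid$origin - spec$spacing / 2) ||
        any(ctr + spec$tumor_radius_mm > grid_hi + spec$spacing / 2))
      stop("tumor sphere exits the grid at phase '",
           spec$phases$labels[p], "'; enlarge the grid or padding")
    rasterize_sphere(ctr, spec$tumor_radius_mm, grid$origin, spec$spacing,
                     grid$shape)
  })
  four_d_study(patient_id, spec$phases, masks, tracks)
}

#' Closed-form expected RMSE for a noise-free phantom
#'
#' Independent analytic ground truth for the RMSE of a marker combination:
#' evaluates the tumor and marker trajectories continuously (no
#' rasterization, no noise) and applies the residual formula
#' `r_p = (T_p - M_p) - (T_ref - M_ref)` per axis, where `M` is the mean of
#' the subset's trajectories, then takes the root mean square over the
#' non-reference phases.
#'
#' @param spec A [phantom_spec()] whose tumor and subset markers all have
#'   `noise_sd = 0`.
#' @param subset Character vector of marker ids in `spec$markers`.
#' @return Named numeric length-3 RMSE (mm) per direction.
#' @export
analytic_residual_rmse <- function(spec, subset = names(spec$markers)) {
  stopifnot(inherits(spec, "phantom_spec"))
  missing_ids <- setdiff(subset, names(spec$markers))
  if (length(missing_ids))
    stop("unknown marker id(s): ", paste(missing_ids, collapse = ", "))
  cfgs <- c(list(spec$tumor), spec$markers[subset])
  for (cfg in cfgs)
    if (any(cfg$noise_sd > 0))
      stop("analytic_residual_rmse is a deterministic oracle: ",
           "all noise_sd must be 0")
  tumor <- noise_free_trajectory(spec$tumor, spec$phases)
  mc <- Reduce(`+`, lapply(spec$markers[subset], noise_free_trajectory,
                           phases = spec$phases)) / length(subset)
  ref <- spec$phases$reference_index
  res <- sweep(tumor - mc, 2, tumor[ref, ] - mc[ref, ])
  rmse <- sqrt(colMeans(res[-ref, , drop = FALSE]^2))
  names(rmse) <- c("lr_mm", "ap_mm", "si_mm")
  rmse
}
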