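# Small in-code fixtures shared across test files.

# Study whose GTV mask at each phase is a single voxel at an integer-mm
# position: mask centroids are then exact, so algebraic expectations hold
# to machine precision.
point_study <- function(gtv_pos, markers, patient_id = "pt",
                        phases = phase_set()) {
  gtv_pos <- as.matrix(gtv_pos)
  origin <- apply(gtv_pos, 2, min) - 1
  shape <- apply(gtv_pos, 2, max) - origin + 2
  masks <- lapply(seq_len(nrow(gtv_pos)), function(p) {
    occ <- array(FALSE, dim = shape)
    idx <- gtv_pos[p, ] - origin + 1
    occ[idx[1], idx[2], idx[3]] <- TRUE
    voxel_mask(occ, spacing = c(1, 1, 1), origin = origin)
  })
  four_d_study(patient_id, phases, masks, markers)
}

# constant-position track helper
static_track <- function(pos, np = 10) {
  matrix(rep(pos, each = np), np, 3)
}

# two-marker phantom spec with shared tumor/marker waveform parameters
sync_spec <- function(amplitude = c(1, 2, 8), lag = c(0, 0), seed = 1,
                      noise_sd = 0, spacing = c(1, 1, 1), radius = 6,
                      waveform = "sinusoid") {
  tum <- motion_config(amplitude = amplitude, waveform = waveform,
                       noise_sd = noise_sd)
  mks <- list(
    m1 = motion_config(amplitude = amplitude, phase_lag = lag[1],
                       baseline = c(20, 0, 0), noise_sd = noise_sd,
                       waveform = waveform),
    m2 = motion_config(amplitude = amplitude, phase_lag = lag[2],
                       baseline = c(-20, 0, 0), noise_sd = noise_sd,
                       waveform = waveform))
  phantom_spec(tum, mks, tumor_radius_mm = radius, spacing = spacing,
               seed = seed)
}

# cohort used by the acceptance-level checks; built once per test run
cached_tle_cohort <- local({
  cache <- NULL
  function(seed = 101) {
    if (is.null(cache)) cache <<- simulate_cohort(seed)
    cache
  }
})
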