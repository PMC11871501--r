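blob_mask <- function(seed = 1, dim = c(14, 14, 10), spacing = c(1, 1, 2)) {
  set.seed(seed)
  occ <- array(FALSE, dim = dim)
  occ[4:9, 5:10, 3:7] <- runif(6 * 6 * 5) > 0.5
  voxel_mask(occ, spacing = spacing)
}

test_that("shift snapping rounds half away from zero and logs the remainder", {
  m <- blob_mask()
  s0 <- shift_mask(m, c(0, 0, 0))
  expect_identical(s0$occupancy, m$occupancy)

  # one full voxel per axis
  s1 <- shift_mask(pad_mask(m, c(1, 1, 2)), c(1, 1, 2))
  expect_equal(attr(s1, "offset_voxels"), c(1L, 1L, 1L))
  expect_equal(mask_volume(s1), mask_volume(m))

  # 0.4 of a voxel: zero offset, remainder recorded
  s2 <- shift_mask(m, c(0.4, 0, 0))
  expect_equal(attr(s2, "offset_voxels"), c(0L, 0L, 0L))
  expect_equal(attr(s2, "remainder_mm"), c(0.4, 0, 0))
  expect_identical(s2$occupancy, m$occupancy)

  # exactly half a voxel rounds away from zero, both signs
  s3 <- shift_mask(pad_mask(m, 2), c(0.5, -0.5, 0))
  expect_equal(attr(s3, "offset_voxels"), c(1L, -1L, 0L))

  # occupied voxels pushed off the grid raise an error mentioning padding
  expect_error(shift_mask(m, c(50, 0, 0)), "pad")
})

test_that("shift conserves volume for any in-grid shift", {
  m <- blob_mask(2)
  for (seed in 1:8) {
    set.seed(seed)
    v <- runif(3, -4, 4)
    s <- shift_mask(pad_mask(m, 10), v)
    expect_equal(mask_volume(s), mask_volume(m))
  }
})

test_that("union matches brute-force voxelwise OR and its volume bounds", {
  a <- rasterize_sphere(c(0, 0, 0), 5, c(-10, -10, -10), c(1, 1, 1),
                        c(21L, 21L, 21L))
  b <- rasterize_sphere(c(4, 0, 0), 5, c(-10, -10, -10), c(1, 1, 1),
                        c(21L, 21L, 21L))
  u <- union_masks(list(a, b))
  # brute-force OR loop
  n <- 0L
  for (i in seq_along(a$occupancy))
    if (a$occupancy[i] || b$occupancy[i]) n <- n + 1L
  expect_equal(sum(u$occupancy), n)
  expect_identical(union_masks(list(a, a))$occupancy, a$occupancy)
  expect_gte(mask_volume(u), max(mask_volume(a), mask_volume(b)))
  expect_lte(mask_volume(u), mask_volume(a) + mask_volume(b))

  # disjoint blobs add exactly
  c2 <- rasterize_sphere(c(0, 0, 0), 2, c(-10, -10, -10), c(1, 1, 1),
                         c(21L, 21L, 21L))
  d2 <- rasterize_sphere(c(8, 8, 8), 2, c(-10, -10, -10), c(1, 1, 1),
                         c(21L, 21L, 21L))
  expect_equal(mask_volume(union_masks(list(c2, d2))),
               mask_volume(c2) + mask_volume(d2))
  expect_error(union_masks(list(a, blob_mask())), "one grid")
})

test_that("margin expansion matches the brute-force ellipsoid distance rule", {
  occ <- array(FALSE, dim = c(15, 15, 15))
  occ[8, 8, 8] <- TRUE
  m <- voxel_mask(occ, spacing = c(1, 1, 1), origin = c(0, 0, 0))

  expect_identical(expand_mask(m, c(0, 0, 0))$occupancy, m$occupancy)

  e <- expand_mask(m, c(5, 5, 5))
  n_brute <- 0L
  for (i in 1:15) for (j in 1:15) for (k in 1:15)
    if (sum((c(i, j, k) - c(8, 8, 8))^2) <= 25) n_brute <- n_brute + 1L
  expect_equal(sum(e$occupancy), n_brute)

  # anisotropic margins with a zero axis admit no motion on that axis
  e2 <- expand_mask(m, c(3, 0, 1))
  idx <- which(e2$occupancy, arr.ind = TRUE)
  expect_true(all(idx[, 2] == 8))
  expect_true(all(abs(idx[, 1] - 8) <= 3))
  expect_true(all((idx[, 1] - 8)^2 / 9 + (idx[, 3] - 8)^2 / 1 <= 1 + 1e-9))
})

test_that("expanded sphere contains the analytically grown sphere", {
  orig <- c(-15, -15, -15); shp <- c(31L, 31L, 31L)
  r <- 6; mgn <- 4
  small <- rasterize_sphere(c(0, 0, 0), r, orig, c(1, 1, 1), shp)
  grown <- expand_mask(small, rep(mgn, 3))
  target <- rasterize_sphere(c(0, 0, 0), r + mgn - 1, orig, c(1, 1, 1), shp)
  expect_true(all(grown$occupancy[target$occupancy]))
})

test_that("expansion is monotone in every margin component", {
  m <- blob_mask(3)
  base <- expand_mask(pad_mask(m, 6), c(2, 1, 2))
  for (d in list(c(1, 0, 0), c(0, 1.5, 0), c(0, 0, 2), c(1, 1, 1))) {
    bigger <- expand_mask(pad_mask(m, 6), c(2, 1, 2) + d)
    expect_true(all(bigger$occupancy[base$occupancy]))
  }
})

test_that("static study union equals the reference GTV", {
  tum <- motion_config()
  mks <- list(m1 = motion_config(baseline = c(12, 0, 0)),
              m2 = motion_config(baseline = c(-12, 0, 0)))
  st <- build_phantom(phantom_spec(tum, mks, tumor_radius_mm = 5,
                                   spacing = c(1, 1, 1), seed = 2))
  u <- build_gtv_union_shift(st)
  expect_equal(mask_volume(u),
               mask_volume(st$gtv_masks[[st$phases$reference_index]]))
})

test_that("synchronous phantom union stays within rasterization of the GTV", {
  st <- build_phantom(sync_spec(seed = 17, radius = 8))
  u <- build_gtv_union_shift(st)
  ref_vol <- mask_volume(st$gtv_masks[[st$phases$reference_index]])
  # perfect alignment: union exceeds the reference only through voxel
  # snapping of the shifts (sub-voxel skin around the sphere)
  expect_lt(mask_volume(u) / ref_vol, 1.25)
  expect_gte(mask_volume(u) / ref_vol, 1)
})

test_that("asynchronous phantom union elongates by about the SI residual", {
  # markers static, tumor oscillates 4 mm SI: residual = full tumor motion
  tum <- motion_config(amplitude = c(0, 0, 4))
  mks <- list(m1 = motion_config(baseline = c(12, 0, 0)),
              m2 = motion_config(baseline = c(-12, 0, 0)))
  st <- build_phantom(phantom_spec(tum, mks, tumor_radius_mm = 5,
                                   spacing = c(1, 1, 1), seed = 3))
  u <- build_gtv_union_shift(st)
  extent <- function(mask) {
    idx <- which(mask$occupancy, arr.ind = TRUE)
    (max(idx[, 3]) - min(idx[, 3])) * mask$spacing[3]
  }
  growth <- extent(u) - extent(st$gtv_masks[[st$phases$reference_index]])
  # peak-to-peak SI trajectory spread over discrete phases
  expected <- diff(range(4 * sin(2 * pi * (0:9) / 10)))
  expect_lt(abs(growth - expected), 1.5)
})

test_that("target comparison metrics behave at the edges", {
  st <- build_phantom(sync_spec(seed = 19, radius = 6))
  ts <- make_target_set(st, tle_margin = c(2, 2.1, 3.2), ptv_margin_mm = 5)
  # nested structures by construction
  expect_true(all(ts$gtv_tle_ref$occupancy[ts$gtv_ref$occupancy]))
  expect_true(all(ts$ptv_tle_ref$occupancy[ts$gtv_tle_ref$occupancy]))
  cmp <- compare_targets(ts)
  expect_gte(cmp$coverage_fraction_geometric, 0)
  expect_lte(cmp$coverage_fraction_geometric, 1)
  expect_gt(cmp$r_v_union_ref, 0)

  # synchronous phantom with margins: full containment
  expect_equal(cmp$coverage_fraction_geometric, 1)

  # degenerate target set: identical structures give ratio 1, distance 0
  ts2 <- ts
  ts2$gtv_union_shift <- ts$gtv_tle_ref
  cmp2 <- compare_targets(ts2)
  expect_equal(cmp2$r_v_union_ref, 1)
  expect_equal(cmp2$centroid_distance_mm, 0)
  expect_equal(cmp2$coverage_fraction_geometric, 1)
})

test_that("asynchrony beyond the margins produces under-coverage", {
  # tumor swings 24 mm SI against static markers; margins absorb ~8 mm
  tum <- motion_config(amplitude = c(0, 0, 12))
  mks <- list(m1 = motion_config(baseline = c(12, 0, 0)),
              m2 = motion_config(baseline = c(-12, 0, 0)))
  st <- build_phantom(phantom_spec(tum, mks, tumor_radius_mm = 5,
                                   spacing = c(1, 1, 2.5), seed = 4))
  ts <- make_target_set(st, tle_margin = c(2, 2.1, 3.2), ptv_margin_mm = 5)
  cmp <- compare_targets(ts)
  expect_lt(cmp$coverage_fraction_geometric, 1)
  # exact voxel count by an explicit intersection loop
  n_in <- 0L; n_tot <- 0L
  occ_u <- ts$gtv_union_shift$occupancy
  occ_p <- ts$ptv_tle_ref$occupancy
  for (i in seq_along(occ_u)) if (occ_u[i]) {
    n_tot <- n_tot + 1L
    if (occ_p[i]) n_in <- n_in + 1L
  }
  expect_equal(cmp$coverage_fraction_geometric, n_in / n_tot)
})
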