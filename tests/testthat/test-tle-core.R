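test_that("combination enumeration is exhaustive and deterministically ordered", {
  ids5 <- paste0("m", 1:5)
  combos <- enumerate_combinations(ids5)
  sizes <- lengths(combos)
  expect_equal(sum(sizes == 2), 10)          # choose(5, 2)
  expect_equal(length(combos), 2^5 - 5 - 1)  # all subsets of size >= 2
  expect_equal(sizes, sort(sizes))           # ordered by size
  # lexicographic within size
  pair_keys <- sapply(combos[sizes == 2], paste, collapse = ",")
  expect_equal(pair_keys, sort(pair_keys))

  expect_equal(enumerate_combinations(c("b", "a")), list(c("a", "b")))
  expect_equal(length(enumerate_combinations(paste0("m", 1:4))), 11) # 6+4+1
  expect_error(enumerate_combinations("m1"), "at least 2")
  # order is independent of input ordering
  expect_identical(enumerate_combinations(rev(ids5)),
                   enumerate_combinations(ids5))
})

test_that("combination centroid is the component-wise mean", {
  st <- point_study(static_track(c(0, 0, 0)),
                    list(a = static_track(c(0, 0, 0)),
                         b = static_track(c(2, 4, 6)),
                         c = static_track(c(7, -2, 5))))
  expect_equal(unname(combination_centroid(st, c("a", "b"), 1)), c(1, 2, 3))
  expect_equal(unname(combination_centroid(st, c("a", "b", "c"), "30%")),
               c(0 + 2 + 7, 0 + 4 - 2, 0 + 6 + 5) / 3)
  expect_error(combination_centroid(st, c("a", "zz"), 1), "no marker")
})

test_that("alignment shift moves the phase marker centroid onto the reference", {
  tracks <- list(a = static_track(c(0, 0, 0)), b = static_track(c(0, 0, 0)))
  tracks$a[2, ] <- c(1, -2, 3)   # phase '10%', non-reference
  tracks$b[2, ] <- c(1, -2, 3)
  st <- point_study(static_track(c(0, 0, 0)), tracks)
  expect_equal(unname(alignment_shift(st, c("a", "b"), 2)), c(-1, 2, -3))
  expect_equal(unname(alignment_shift(st, c("a", "b"), "30%")), c(0, 0, 0))
})

test_that("alignment shift reproduces the reference centroid on a phantom", {
  st <- build_phantom(sync_spec(lag = c(0.05, -0.03), seed = 13))
  ref <- combination_centroid(st, c("m1", "m2"), st$phases$reference_index)
  for (p in 1:10) {
    s <- alignment_shift(st, c("m1", "m2"), p)
    expect_equal(combination_centroid(st, c("m1", "m2"), p) + s, ref,
                 tolerance = 1e-12)
  }
})

test_that("RMSE follows the per-direction residual formula with N = 9", {
  np <- 10
  # identical tumor and marker trajectories: zero RMSE
  traj <- static_track(c(0, 0, 0))
  traj[, 3] <- 3 * sin(2 * pi * (0:9) / 10)
  st <- point_study(round(traj), list(a = round(traj), b = round(traj)))
  expect_equal(unname(rmse_per_direction(st, c("a", "b"))), c(0, 0, 0))

  # constant +1 mm SI residual at every non-reference phase
  gtv <- static_track(c(0, 0, 0))
  gtv[-4, 3] <- 1
  st <- point_study(gtv, list(a = static_track(c(5, 0, 0)),
                              b = static_track(c(-5, 0, 0))))
  expect_equal(unname(rmse_per_direction(st, c("a", "b"))), c(0, 0, 1))

  # single 3 mm SI excursion in one of the 9 phases: sqrt(9/9) = 1,
  # pinning the divisor to the number of non-reference phases
  gtv <- static_track(c(0, 0, 0))
  gtv[1, 3] <- 3
  st <- point_study(gtv, list(a = static_track(c(5, 0, 0)),
                              b = static_track(c(-5, 0, 0))))
  expect_equal(unname(rmse_per_direction(st, c("a", "b"))),
               c(0, 0, sqrt(9 / 9)))
})

test_that("RMSE is invariant to per-phase and global translations", {
  st <- build_phantom(sync_spec(lag = c(0.06, -0.02), seed = 21))
  base <- rmse_per_direction(st, c("m1", "m2"))

  # translate one phase's structures (masks stay put; markers and tumor
  # centroid move together is emulated by shifting marker track and mask)
  st2 <- st
  delta <- c(4, -3, 2)   # whole voxels so the mask shift is exact
  st2$markers$m1[6, ] <- st2$markers$m1[6, ] + delta
  st2$markers$m2[6, ] <- st2$markers$m2[6, ] + delta
  st2$gtv_masks[[6]] <- shift_mask(pad_mask(st2$gtv_masks[[6]], 6), delta)
  # re-pad every other mask so grids stay consistent for validity
  expect_equal(unname(rmse_per_direction(st2, c("m1", "m2"))),
               unname(base), tolerance = 1e-9)

  # global translation of everything
  st3 <- st
  for (id in marker_ids(st3))
    st3$markers[[id]] <- st3$markers[[id]] +
      matrix(rep(c(7, 7, 7), each = 10), 10, 3)
  for (p in 1:10) st3$gtv_masks[[p]]$origin <-
      st3$gtv_masks[[p]]$origin + c(7, 7, 7)
  expect_equal(rmse_per_direction(st3, c("m1", "m2")), base,
               tolerance = 1e-9)
})

test_that("RMSE is invariant to marker order within a combination", {
  st <- build_phantom(sync_spec(lag = c(0.08, -0.05), seed = 31))
  expect_equal(rmse_per_direction(st, c("m1", "m2")),
               rmse_per_direction(st, c("m2", "m1")))
})

test_that("mask-shift evaluation agrees with the centroid shortcut", {
  st <- build_phantom(sync_spec(amplitude = c(2, 3, 10),
                                lag = c(0.1, -0.06), seed = 41))
  a <- rmse_per_direction(st, c("m1", "m2"), method = "centroid")
  b <- rmse_per_direction(st, c("m1", "m2"), method = "mask")
  half_diag <- sqrt(sum((st$gtv_masks[[1]]$spacing / 2)^2))
  expect_lt(max(abs(a - b)), half_diag)
})

test_that("TLE pooling reports range, SD and interpolated P95 per group", {
  mk <- function(vals, k) data.frame(
    patient_id = "p", marker_ids = "x", k = k,
    rmse_lr = vals, rmse_ap = vals, rmse_si = vals,
    dist_lr = 1, dist_ap = 1, dist_si = 1, dist_3d = 1,
    motion_lr = 1, motion_ap = 1, motion_si = 1)

  # all values equal: TLE = the value, SD = 0
  rep1 <- pool_tle(mk(rep(2.5, 6), 2))
  expect_equal(rep1$tle, rep(2.5, 6))
  expect_equal(rep1$rmse_sd, rep(0, 6))

  # pooled 1..20: P95 = 19.05 under linear order-statistic interpolation
  rep2 <- pool_tle(mk(1:20, 2))
  expect_equal(rep2$tle[rep2$group == "All" & rep2$direction == "SI"], 19.05)

  # population vs sample SD conventions
  x <- c(1, 2, 3, 6)
  rep3 <- pool_tle(mk(x, 2))
  expect_equal(rep3$rmse_sd[1], sqrt(mean((x - mean(x))^2)))
  rep4 <- pool_tle(mk(x, 2), sd_divisor = "n-1")
  expect_equal(rep4$rmse_sd[1], sd(x))

  # P95 bounded by min/max; monotone when a new maximum is appended
  expect_true(all(rep2$tle >= rep2$rmse_min & rep2$tle <= rep2$rmse_max))
  rep5 <- pool_tle(mk(c(1:20, 50), 2))
  expect_gt(rep5$tle[1], rep2$tle[1])
})

test_that("report groups follow the marker-count structure", {
  res <- rbind(
    do.call(rbind, replicate(3, data.frame(
      patient_id = "a", marker_ids = "x", k = 2,
      rmse_lr = runif(1), rmse_ap = runif(1), rmse_si = runif(1),
      dist_lr = 1, dist_ap = 1, dist_si = 1, dist_3d = 1,
      motion_lr = 1, motion_ap = 1, motion_si = 1), simplify = FALSE)),
    data.frame(patient_id = "b", marker_ids = "y", k = 3,
               rmse_lr = 1, rmse_ap = 1, rmse_si = 1,
               dist_lr = 1, dist_ap = 1, dist_si = 1, dist_3d = 1,
               motion_lr = 1, motion_ap = 1, motion_si = 1))
  rep <- pool_tle(res)
  expect_setequal(unique(rep$group), c("Two", "Three", "All"))
  expect_equal(unique(rep$n[rep$group == "Two"]), 3)
  expect_equal(unique(rep$n[rep$group == "All"]), 4)
  m <- tle_margins(rep)
  expect_named(m, c("lr_mm", "ap_mm", "si_mm"))
  expect_error(tle_margins(rep, "Five"), "no group")
})
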