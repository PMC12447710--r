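cube_mask <- function(dims, lo, hi) {
  m <- array(FALSE, dims)
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  m
}

test_that("DSC matches counting and degenerate conventions", {
  d <- c(6L, 6L, 6L)
  a <- cube_mask(d, c(2, 2, 2), c(3, 3, 2))   # 4 voxels
  b <- cube_mask(d, c(2, 2, 2), c(3, 3, 3))   # 8 voxels, contains a
  expect_equal(dsc(a, b), 2 * 4 / 12)
  expect_equal(dsc(b, b), 1)
  expect_equal(dsc(a, cube_mask(d, c(5, 5, 5), c(6, 6, 6))), 0)
  expect_equal(dsc(array(FALSE, d), array(FALSE, d)), 1)
  expect_equal(dsc(a, array(FALSE, d)), 0)
  expect_error(dsc(a, array(FALSE, c(5, 5, 5))), "grid mismatch")
  # symmetry
  expect_equal(dsc(a, b), dsc(b, a))
})

test_that("surface metrics agree with the exhaustive all-pairs oracle on small grids", {
  set.seed(12)
  cases <- list(
    list(p = cube_mask(c(10L, 10L, 10L), c(3, 3, 3), c(6, 6, 6)),
         r = cube_mask(c(10L, 10L, 10L), c(4, 3, 3), c(7, 6, 6)),
         sp = c(1, 1, 1)),  # cube shifted by 1 voxel
    list(p = cube_mask(c(16L, 10L, 8L), c(2, 2, 2), c(5, 5, 4)),
         r = cube_mask(c(16L, 10L, 8L), c(7, 2, 2), c(10, 5, 4)),
         sp = c(1, 1, 1)),  # cube shifted by 5 voxels
    list(p = cube_mask(c(9L, 9L, 9L), c(2, 2, 2), c(4, 6, 5)),
         r = cube_mask(c(9L, 9L, 9L), c(3, 4, 2), c(7, 8, 6)),
         sp = c(1.5, 1.5, 3)))  # anisotropic spacing
  for (i in 1:3) {
    m <- array(runif(12^3) < 0.3, c(12L, 12L, 12L))
    r <- array(runif(12^3) < 0.3, c(12L, 12L, 12L))
    cases[[length(cases) + 1L]] <- list(p = m, r = r, sp = c(1, 2, 1))
  }
  for (cs in cases) {
    tol_mm <- 2 * mean(cs$sp)
    want <- oracle_surface_metrics(cs$p, cs$r, cs$sp, tol_mm)
    expect_equal(hd95(cs$p, cs$r, cs$sp), want$hd95, tolerance = 1e-9)
    expect_equal(msd(cs$p, cs$r, cs$sp), want$msd, tolerance = 1e-9)
    expect_equal(surface_dice(cs$p, cs$r, cs$sp, tolerance = 2), want$sdice,
                 tolerance = 1e-9)
    # MSD never exceeds the maximum surface distance; symmetry of MSD
    expect_lte(msd(cs$p, cs$r, cs$sp), hd95(cs$p, cs$r, cs$sp, percentile = 1))
    expect_equal(msd(cs$p, cs$r, cs$sp), msd(cs$r, cs$p, cs$sp),
                 tolerance = 1e-12)
  }
})

test_that("surface metric conventions: identity, 1-voxel shift, emptiness", {
  d <- c(10L, 10L, 10L)
  a <- cube_mask(d, c(3, 3, 3), c(6, 6, 6))
  b <- cube_mask(d, c(4, 3, 3), c(7, 6, 6))
  expect_equal(hd95(a, a, c(1, 1, 1)), 0)
  expect_equal(msd(a, a, c(1, 1, 1)), 0)
  expect_equal(surface_dice(a, a, c(1, 1, 1)), 1)
  # shift by 1 voxel with tolerance 2: every surface point within reach
  expect_equal(surface_dice(a, b, c(1, 1, 1), tolerance = 2), 1)
  # empty prediction: NA value feeds the failure/discard rule
  expect_true(is.na(hd95(array(FALSE, d), a, c(1, 1, 1))))
  expect_true(is.na(msd(a, array(FALSE, d), c(1, 1, 1))))
  expect_equal(hd95(array(FALSE, d), array(FALSE, d), c(1, 1, 1)), 0)
})

test_that("skeletonization thins tubes to centerlines and is conservative", {
  d <- c(26L, 9L, 9L)
  # a 1-voxel line is its own skeleton
  ln <- array(FALSE, d); ln[3:20, 5, 5] <- TRUE
  expect_identical(skeletonize_mask(ln), ln)
  # a radius-2, length-20 tube thins to a path along its axis
  tube <- array(FALSE, d)
  for (x in 4:23) for (y in 1:9) for (z in 1:9)
    if ((y - 5)^2 + (z - 5)^2 <= 4) tube[x, y, z] <- TRUE
  sk <- skeletonize_mask(tube)
  expect_true(all(tube[sk]))                    # skeleton subset of mask
  w <- which(sk, arr.ind = TRUE)
  expect_gte(nrow(w), 15); expect_lte(nrow(w), 25)
  expect_true(all(abs(w[, 2] - 5) <= 1 & abs(w[, 3] - 5) <= 1))
  expect_identical(sum(skeletonize_mask(array(FALSE, d))), 0L)
  # deterministic
  expect_identical(skeletonize_mask(tube), sk)
})

test_that("centerline Dice matches hand-counted topology precision/sensitivity", {
  d <- c(24L, 7L, 7L)
  ref <- array(FALSE, d); ref[3:22, 4, 4] <- TRUE    # 20-voxel line
  expect_equal(centerline_dice(ref, ref), 1)
  # prediction covering exactly half the reference length, inside it
  pred <- array(FALSE, d); pred[3:12, 4, 4] <- TRUE
  # Tprec = 1 (pred skeleton inside ref), Tsens = 0.5
  expect_equal(centerline_dice(pred, ref), 2 * 0.5 / 1.5, tolerance = 1e-12)
  # disjoint tubes
  other <- array(FALSE, d); other[3:22, 2, 2] <- TRUE
  expect_equal(centerline_dice(other, ref), 0)
  expect_true(is.na(centerline_dice(array(FALSE, d), ref)))
  expect_equal(centerline_dice(array(FALSE, d), array(FALSE, d)), 1)
})

test_that("evaluate_case produces 84 records with the discard rule applied", {
  anat <- fixture_anatomy(3)
  recs <- evaluate_case(anat, anat, case = "self")
  expect_identical(nrow(recs), 20L * 4L + 4L)
  expect_true(all(recs$value[recs$metric == "dsc"] == 1))
  expect_true(all(recs$value[recs$metric %in% c("hd95", "msd")] == 0))
  expect_true(all(recs$value[recs$metric == "cldice"] == 1))
  expect_false(any(recs$failed))
  # ablate one structure from the prediction: distances fail, DSC = 0
  broken <- anat$masks
  broken[["N-AV"]] <- array(FALSE, dim(broken[["N-AV"]]))
  pred <- composite_segmentation(broken, anat$spacing, anat$catalog)
  recs2 <- evaluate_case(pred, anat, case = "ablated")
  nav <- recs2[recs2$structure == "N-AV", ]
  expect_equal(nav$value[nav$metric == "dsc"], 0)
  expect_true(all(nav$failed[nav$metric %in% c("hd95", "msd")]))
  expect_true(all(is.na(nav$value[nav$metric %in% c("hd95", "msd")])))
  # failure flags never coexist with finite values
  expect_false(any(recs2$failed & is.finite(recs2$value)))
})
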