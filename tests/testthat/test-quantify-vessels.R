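test_that("Mexican-hat enhancement kills constants and peaks on ridge centerlines", {
  const <- matrix(0.4, 40, 40)
  expect_true(all(enhance_vessels(const, scales_um = 40,
                                  spacing_um = 10)$image == 0))
  ridge <- matrix(0, 60, 41)
  ridge[, 19:23] <- 1                      # width-5 ridge along x
  r1 <- enhance_vessels(ridge, scales_um = 50, spacing_um = 10)$image
  expect_equal(unname(which.max(r1[30, ])), 21)  # maximal on the centerline
  # DC invariance
  r2 <- enhance_vessels(ridge + 0.25, scales_um = 50, spacing_um = 10)$image
  expect_equal(r1, r2, tolerance = 1e-8)
  expect_error(enhance_vessels(ridge, scales_um = 5, spacing_um = 10),
               "below one pixel")
  expect_error(enhance_vessels(ridge, scales_um = numeric(0)), "non-empty")
})

test_that("binarization separates levels, warns on constant input, and prunes specks", {
  two <- matrix(0.1, 20, 20)
  two[6:15, 6:15] <- 0.9
  b <- binarize_vessels(two, method = "otsu", min_area_px = 1)
  expect_identical(b$mask, two > 0.5)
  bf <- binarize_vessels(matrix(c(0.4, 0.6), 10, 10), method = "fixed",
                         fixed_threshold = 0.5, min_area_px = 1)
  expect_identical(bf$mask, matrix(c(FALSE, TRUE), 10, 10))
  expect_warning(bc <- binarize_vessels(matrix(0.3, 8, 8)), "constant")
  expect_false(any(bc$mask))
  expect_error(binarize_vessels(two, method = "fixed"), "fixed_threshold")
  # small-object removal
  sp <- matrix(0, 30, 30)
  sp[5:20, 5:9] <- 1; sp[25, 25] <- 1      # one bar, one speck
  bs <- binarize_vessels(sp, method = "fixed", fixed_threshold = 0.5,
                         min_area_px = 5)
  expect_false(bs$mask[25, 25])
  expect_true(all(bs$mask[5:20, 5:9]))
})

test_that("vessel density equals a brute-force pixel count and respects the roi", {
  m <- matrix(FALSE, 20, 20)
  expect_equal(vessel_density(m), 0)
  m[, 1:10] <- TRUE
  expect_equal(vessel_density(m), 50)
  set.seed(7)
  r <- matrix(runif(40 * 30) < 0.3, 40, 30)
  expect_equal(vessel_density(r), 100 * sum(r) / length(r))
  roi <- c(5L, 24L, 3L, 22L)
  expect_equal(vessel_density(r, roi = roi),
               100 * sum(r[5:24, 3:22]) / 400)
})

test_that("skeleton-and-distance-transform diameters recover drawn tube widths", {
  # 10 px wide bar at 10 um/px: 100 um, constant width away from the ends
  vm <- measure_diameters(draw_bar(10), spacing_um = 10, sample_step_px = 5)
  expect_lt(abs(vm$diameter_mean_um - 100), 10)
  expect_equal(vm$diameter_sd_um, 0)
  expect_gte(vm$n_measurements, 1)
  # widths 3..15: within 1 px of truth each
  for (w in c(3, 5, 8, 11, 15)) {
    vmw <- measure_diameters(draw_bar(w), spacing_um = 10, sample_step_px = 3)
    expect_lte(abs(vmw$diameter_mean_um - w * 10), 10 + 1e-9)
  }
  # two bars of widths 4 and 8 with equal lengths average to ~6 px
  m <- matrix(FALSE, 80, 60)
  m[10:70, 11:14] <- TRUE
  m[10:70, 41:48] <- TRUE
  vm2 <- measure_diameters(m, spacing_um = 10, sample_step_px = 3)
  expect_lt(abs(vm2$diameter_mean_um - 60), 10)
  expect_error(measure_diameters(matrix(FALSE, 5, 5)), "no vessels")
})

test_that("skeletonization returns a thin centerline inside the mask", {
  m <- draw_bar(9)
  sk <- skeletonize(m)
  expect_true(all(m[sk]))                      # skeleton subset of mask
  expect_true(any(sk))
  # away from the bar ends: exactly one skeleton pixel per cross-section
  core <- sk[20:60, ]
  expect_true(all(rowSums(core) == 1))
})
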