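test_that("IBDV hand values: identical frames give zero, the (2,1) pair gives 0.2", {
  frames <- array(rep(runif(12, 0.2, 1), 4), dim = c(3, 4, 4))
  expect_equal(max(abs(compute_ibdv(frames, window = 0))), 0)
  expect_equal(max(abs(compute_ibdv(frames, window = 2, depth_window = 1))), 0)

  pair <- array(c(2, 1), dim = c(1, 1, 2))
  expect_equal(compute_ibdv(pair, window = 0)[1, 1], 0.2)

  expect_error(compute_ibdv(array(1, dim = c(2, 2, 1))), "at least two")
  # zero-signal voxels are defined as zero, not NaN
  z <- array(0, dim = c(2, 2, 3))
  expect_equal(compute_ibdv(z, window = 0), matrix(0, 2, 2))
})

test_that("IBDV is scale invariant, bounded, and matches a scalar oracle at window 0", {
  set.seed(41)
  frames <- array(rexp(6 * 8 * 2) + 0.01, dim = c(6, 8, 2))
  s2 <- compute_ibdv(frames, window = 0)
  expect_true(all(s2 >= 0 & s2 <= 1))
  expect_equal(compute_ibdv(frames * 37.5, window = 0), s2)
  # independent scalar evaluation of the defining formula per voxel
  oracle <- matrix(0, 6, 8)
  for (i in 1:6) for (k in 1:8) {
    a <- frames[i, k, 1]; b <- frames[i, k, 2]
    oracle[i, k] <- 1 - (a * b) / ((a^2 + b^2) / 2)
  }
  expect_equal(s2, pmin(pmax(oracle, 0), 1))
  # complex input: modulus is taken
  expect_equal(compute_ibdv(frames * (0 + 1i), window = 0), s2)
})

test_that("mean IBDV of i.i.d. Rayleigh frames matches an independent Monte-Carlo oracle", {
  set.seed(99)
  n <- 20000
  ray <- function(m) sqrt(stats::rnorm(m, 0, sqrt(0.5))^2 +
                            stats::rnorm(m, 0, sqrt(0.5))^2)
  frames <- array(ray(n * 6), dim = c(n, 1, 6))
  impl_mean <- mean(compute_ibdv(frames, window = 0))
  set.seed(100)
  oracle <- replicate(20000, {
    A <- ray(6)
    num <- sum(A[1:5] * A[2:6])
    den <- sum((A[1:5]^2 + A[2:6]^2) / 2)
    min(1, max(0, 1 - num / den))
  })
  expect_lt(abs(impl_mean - mean(oracle)), 0.02)
})

test_that("intensity mask keeps voxels by mean-amplitude quantile with strict-above ties", {
  sp <- flat_spec(n_lateral = 16, n_depth = 48, n_positions = 2, seed = 3)
  fr <- generate_speckle_frames(sp)
  expect_true(all(intensity_mask(fr, 0)))
  # two-level toy volume: quantile 0.5 keeps exactly the bright half
  amp <- array(1, dim = c(4, 4, 2, 2))
  amp[3:4, , , ] <- 2
  toy <- oct_frame_series(amp)
  m <- intensity_mask(toy, 0.5)
  expect_true(all(m[3:4, , ]))
  expect_false(any(m[1:2, , ]))
  expect_error(intensity_mask(toy, 1), "threshold_quantile")
})

test_that("masking at the air fraction removes (almost exactly) the air voxels", {
  sp <- phantom_spec(n_lateral = 48, n_depth = 160, n_positions = 8,
                     vessels = list(), seed = 17)
  fr <- generate_speckle_frames(sp)
  gt <- ground_truth(sp)
  air <- array(FALSE, dim = c(48, 160, 8))
  for (y in 1:8) air[, , y] <- outer(seq_len(48), seq_len(160),
                                     function(i, z) z < gt$surface_z[i, y])
  masked <- !intensity_mask(fr, threshold_quantile = mean(air))
  expect_gt(sum(masked & air) / sum(masked), 0.95)
})

test_that("assembled volumes separate flow from static tissue", {
  sp <- phantom_spec(n_lateral = 64, n_depth = 128, n_positions = 16,
                     vessels = list(vessel_line(c(1, 5, 85), c(64, 5, 85),
                                                radius_um = 90),
                                    vessel_line(c(1, 12, 90), c(64, 12, 90),
                                                radius_um = 70)),
                     seed = 11)
  fr <- generate_speckle_frames(sp)
  vol <- assemble_volume(fr)
  expect_equal(dim(vol$sigma2), c(64, 128, 16))
  gt <- ground_truth(sp)
  vm <- gt$vessel_mask
  in_vessel <- mean(vol$sigma2[vm], na.rm = TRUE)
  static <- array(FALSE, dim = dim(vm))
  for (y in 1:16) static[, , y] <- outer(seq_len(64), seq_len(128),
    function(i, z) z > gt$surface_z[i, y] + 2 & z < gt$dej_z[i, y] - 2)
  out_vessel <- mean(vol$sigma2[static & !vm], na.rm = TRUE)
  expect_gt(in_vessel, 5 * out_vessel)

  # static noise-free phantom: masked-mean sigma2 stays near zero
  sps <- flat_spec(n_positions = 4, noise_floor = 0, seed = 12)
  vols <- assemble_volume(generate_speckle_frames(sps))
  expect_lt(mean(vols$sigma2, na.rm = TRUE), 0.05)

  # single-position series keeps a y-extent of one
  sp1 <- flat_spec(n_lateral = 16, n_depth = 48, n_positions = 1)
  expect_equal(dim(assemble_volume(generate_speckle_frames(sp1))$sigma2)[3],
               1)
})

test_that("en-face MIP projects the maximum over the depth range and handles masked columns", {
  sigma2 <- array(0.1, dim = c(4, 6, 3))
  sigma2[2, 4, 1] <- 0.9
  sigma2[, , 2] <- NaN                    # fully masked position
  vol <- structure(list(sigma2 = sigma2,
                        mask = !is.nan(sigma2),
                        lateral_spacing_um = 40, slow_spacing_um = 40,
                        axial_spacing_um = 5, window = 2, depth_window = 0,
                        threshold_quantile = 0.25),
                   class = "doppler_variance_volume")
  ang <- enface_mip(vol)
  expect_equal(ang$image[2, 1], 0.9)
  expect_true(all(ang$image[, 2] == 0))   # all-NaN columns project to 0
  # single-plane range is the identity on that plane
  one <- enface_mip(vol, c(4, 4))
  expect_equal(one$image[, c(1, 3)], sigma2[, 4, c(1, 3)])
  expect_error(enface_mip(vol, c(5, 3)), "depth_range")
  expect_error(enface_mip(vol, c(0, 2)), "bounds")
})

test_that("a tube's angiogram footprint matches the ground-truth footprint within one pixel", {
  sp <- phantom_spec(n_lateral = 48, n_depth = 128, n_positions = 24,
                     slow_spacing_um = 40,
                     vessels = list(vessel_line(c(1, 12, 80), c(48, 12, 80),
                                                radius_um = 90)),
                     seed = 19)
  fr <- generate_speckle_frames(sp)
  gt <- ground_truth(sp)
  vol <- assemble_volume(fr)
  ang <- enface_mip(vol, c(62, 98))       # slab around the tube
  f <- ang$image > 0.15
  g <- gt$enface_footprint
  expect_true(all(!f | dilate1(g)))       # detections within 1 px of truth
  expect_true(all(!g | dilate1(f)))       # truth covered within 1 px
})
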