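test_that("spec validation rejects bad parameters and names the field", {
  expect_error(phantom_spec(frames_per_position = 1), "frames_per_position")
  expect_error(phantom_spec(axial_spacing_um = 0), "axial_spacing_um")
  expect_error(phantom_spec(dej_contrast = 1.5), "dej_contrast")
  expect_error(phantom_spec(static_correlation = -0.1), "static_correlation")
  expect_error(
    phantom_spec(static_correlation = 0.5,
                 vessels = list(vessel_line(c(1, 1, 50), c(8, 1, 50), 40,
                                            flow_correlation = 0.9))),
    "vessels")
  expect_error(vessel_spec(rbind(c(1, 1, 50), c(9, 1, 50)), radius_um = -3),
               "radius_um")
})

test_that("perfectly static, noise-free tissue yields identical repeats and a fixed seed reproduces frames bit-exactly", {
  sp <- flat_spec(static_correlation = 1, noise_floor = 0, seed = 7)
  fr <- generate_speckle_frames(sp)
  for (j in 2:sp$frames_per_position)
    expect_identical(fr$amplitude[, , j, ], fr$amplitude[, , 1, ])
  fr2 <- generate_speckle_frames(sp)
  expect_identical(fr$amplitude, fr2$amplitude)
  # and a different seed gives different speckle
  fr3 <- generate_speckle_frames(flat_spec(static_correlation = 1,
                                           noise_floor = 0, seed = 8))
  expect_false(identical(fr$amplitude, fr3$amplitude))
})

test_that("speckle amplitudes are Rayleigh and decay exponentially at the set attenuation", {
  sp <- flat_spec(n_depth = 220, n_positions = 4, noise_floor = 0,
                  attenuation_per_um = 0, epithelium_thickness_um = 500,
                  seed = 21)
  fr <- generate_speckle_frames(sp)
  gt <- ground_truth(sp)
  z0 <- ceiling(gt$surface_z[1, 1]) + 2
  a <- as.vector(fr$amplitude[, z0:(z0 + 60), 1, ])[1:10000]
  scale_hat <- sqrt(mean(a^2) / 2)
  ks <- stats::ks.test(a, function(q) 1 - exp(-q^2 / (2 * scale_hat^2)))
  expect_gt(ks$p.value, 0.01)

  sp2 <- flat_spec(n_depth = 220, n_positions = 4, noise_floor = 0,
                   epithelium_thickness_um = 1000, seed = 22)
  fr2 <- generate_speckle_frames(sp2)
  s0 <- ceiling(ground_truth(sp2)$surface_z[1, 1])
  depths <- (s0 + 5):(s0 + 150)
  mean_amp <- vapply(depths, function(z) mean(fr2$amplitude[, z, , ]), 0)
  du <- (depths - ground_truth(sp2)$surface_z[1, 1]) * sp2$axial_spacing_um
  slope <- -stats::coef(stats::lm(log(mean_amp) ~ du))[2]
  expect_lt(abs(slope - sp2$attenuation_per_um) / sp2$attenuation_per_um,
            0.05)
})

test_that("vessel speckle decorrelates to the requested level, monotonically in the mixing coefficient", {
  corr_at <- function(rho) {
    sp <- phantom_spec(n_lateral = 64, n_depth = 128, n_positions = 16,
                       attenuation_per_um = 0, noise_floor = 0,
                       static_correlation = 1,
                       surface = surface_profile(amplitude_um = 0),
                       vessels = list(vessel_line(c(1, 8, 90), c(64, 8, 90),
                                                  radius_um = 80,
                                                  flow_correlation = rho)),
                       seed = 31)
    fr <- generate_speckle_frames(sp)
    vm <- ground_truth(sp)$vessel_mask
    stats::cor(fr$amplitude[, , 1, ][vm], fr$amplitude[, , 2, ][vm])
  }
  cors <- vapply(c(0, 0.25, 0.5, 0.75, 1), corr_at, 0)
  expect_lt(abs(cors[1]), 0.05)          # full decorrelation at rho = 0
  expect_true(all(diff(cors) > 0))       # monotone in the coefficient
  expect_equal(cors[5], 1, tolerance = 1e-9)
})

test_that("ground truth reports exact geometry", {
  # no vessels -> zero density
  expect_equal(ground_truth(flat_spec())$true_density_pct, 0)
  # flat surface at fixed depths: thickness is an arithmetic identity
  sp <- flat_spec(surface = surface_profile(base_depth_um = 245,
                                            amplitude_um = 0),
                  epithelium_thickness_um = 250, axial_spacing_um = 5)
  gt <- ground_truth(sp)
  expect_true(all(abs(gt$true_thickness_um - 250) < 1e-9))
  expect_true(all(abs((gt$dej_z - gt$surface_z) * sp$axial_spacing_um -
                        gt$true_thickness_um) < 1e-9))
  # straight axis-aligned tube: diameter = 2 * radius
  spv <- phantom_spec(n_lateral = 32, n_depth = 96, n_positions = 16,
                      lateral_spacing_um = 10, slow_spacing_um = 10,
                      vessels = list(vessel_line(c(1, 8, 60), c(32, 8, 60),
                                                 radius_um = 50)))
  gtv <- ground_truth(spv)
  expect_equal(gtv$true_diameters_um, 100)
  # footprint width: centres within 50 um of the axis at 10 um spacing
  expect_equal(sum(gtv$enface_footprint[16, ]), 11)
  expect_gt(gtv$true_density_pct, 0)
})

test_that("phantom specs round-trip through YAML", {
  sp <- phantom_spec(n_lateral = 24, n_depth = 48, n_positions = 8,
                     vessels = list(vessel_line(c(1, 4, 30), c(24, 4, 30),
                                                radius_um = 45,
                                                flow_correlation = 0.2)),
                     dej_contrast = 0.7, seed = 13)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_phantom_spec(sp, path)
  sp2 <- read_phantom_spec(path)
  expect_equal(sp2$dej_contrast, sp$dej_contrast)
  expect_equal(sp2$vessels[[1]]$radius_um, 45)
  expect_identical(generate_speckle_frames(sp2)$amplitude,
                   generate_speckle_frames(sp)$amplitude)
})

test_that("frame series round-trip through per-position TIFF stacks", {
  sp <- flat_spec(n_lateral = 16, n_depth = 32, n_positions = 3, seed = 5)
  fr <- generate_speckle_frames(sp)
  dir <- withr::local_tempdir()
  write_frame_series(fr, dir)
  fr2 <- read_frame_series(dir)
  expect_equal(fr2$amplitude, fr$amplitude, tolerance = 1e-6)
  expect_equal(fr2$dt, fr$dt)
  expect_equal(fr2$axial_spacing_um, fr$axial_spacing_um)
})
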