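test_that("FTIR generator produces the documented inclusive grid", {
  s <- generate_ftir_spectrum(age_preset("young_adult"))
  expect_equal(nrow(s), (4000 - 750) / 2 + 1)
  expect_equal(max(s$wavenumber), 4000)
  expect_equal(min(s$wavenumber), 750)
  expect_error(generate_ftir_spectrum(age_preset("newborn"), wn_min = 2000, wn_max = 1000))
})

test_that("noiseless newborn spectrum peaks at 1656 inside the Amide I window", {
  s <- generate_ftir_spectrum(age_preset("newborn"), noise_sd = 0)
  win <- s$wavenumber >= 1600 & s$wavenumber <= 1700
  expect_equal(s$wavenumber[win][which.max(s$absorbance[win])], 1656)
})

test_that("carbohydrate band ratio is larger for old-adult than young-adult", {
  ro <- band_readout(preprocess_spectrum(
    generate_ftir_spectrum(age_preset("old_adult"), noise_sd = 0)))
  ry <- band_readout(preprocess_spectrum(
    generate_ftir_spectrum(age_preset("young_adult"), noise_sd = 0)))
  expect_gt(ro$ratio, ry$ratio)
})

test_that("generators are bit-reproducible under a fixed seed", {
  p <- age_preset("old_adult")
  expect_identical(generate_kinetics(p, noise_sd = 0.01, seed = 5),
                   generate_kinetics(p, noise_sd = 0.01, seed = 5))
  expect_identical(generate_ftir_spectrum(p, noise_sd = 1e-3, seed = 5),
                   generate_ftir_spectrum(p, noise_sd = 1e-3, seed = 5))
  expect_identical(generate_fluorescence(p, 3, 0.05, seed = 5),
                   generate_fluorescence(p, 3, 0.05, seed = 5))
  a <- generate_fiber_stack(p, c(160, 160, 5), seed = 5, n_fibers = 2)
  b <- generate_fiber_stack(p, c(160, 160, 5), seed = 5, n_fibers = 2)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth, b$truth)
})

test_that("reflectance generator respects the wavelength band and noise contract", {
  p <- age_preset("young_adult")
  geom <- detector_geometry()
  expect_error(generate_drs_measurement(p, wavelengths = c(300, 600), geometry = geom),
               "450-1000")
  a <- generate_drs_measurement(p, wavelengths = 600, geometry = geom,
                                n_photons = 1e4, seed = 8)
  b <- generate_drs_measurement(p, wavelengths = 600, geometry = geom,
                                n_photons = 1e4, seed = 8)
  expect_identical(a$reflectance, b$reflectance)
  gt <- ground_truth(a)
  expect_equal(gt$mus_prime, 1.2 * (600 / 550)^(-1.2))
})

test_that("young-adult gels backscatter more than old-adult at the shortest distance", {
  geom <- detector_geometry()
  y <- generate_drs_measurement(age_preset("young_adult"), 600, geom,
                                n_photons = 3e4, seed = 9)
  o <- generate_drs_measurement(age_preset("old_adult"), 600, geom,
                                n_photons = 3e4, seed = 9)
  expect_gt(y$reflectance[y$distance_um == 1100], o$reflectance[o$distance_um == 1100])
})

test_that("a reflectance generator backed by a LUT matches the direct power law", {
  lut <- test_lut()
  p <- age_preset("newborn")
  prof <- generate_drs_measurement(p, c(550, 700, 900), lut$geometry, lut = lut)
  musp_true <- preset_mus_prime(p, c(550, 700, 900))$mus_prime
  for (i in seq_along(musp_true)) {
    expect_equal(prof$reflectance[prof$wavelength_nm == c(550, 700, 900)[i]],
                 lut_interpolate(lut, musp_true[i]))
  }
})

test_that("fiber stacks honor the imaging geometry and ground truth arithmetic", {
  p <- age_preset("young_adult")
  # 20 um at 0.5 um steps -> 41 slices
  fs <- generate_fiber_stack(p, c(128, 128, 41), z_step = 0.5, seed = 2, n_fibers = 3)
  expect_equal(dim(fs$stack$voxels)[3], 41)
  # ground-truth length is the centerline arc length times the pixel size
  with(fs$truth, expect_equal(length_um,
                              sqrt((x1 - x0)^2 + (y1 - y0)^2) * 0.26))
  # empty network: noise-only stack
  empty <- generate_fiber_stack(p, c(96, 96, 5), seed = 2, n_fibers = 0)
  expect_equal(nrow(empty$truth), 0)
  expect_equal(glance(analyze_stack(empty$stack))$fiber_count, 0)
})

test_that("infeasible fiber packing is rejected with a diagnostic", {
  expect_error(
    generate_fiber_stack(age_preset("newborn"), c(72, 72, 5), seed = 1,
                         n_fibers = 40, max_attempts = 10),
    "too crowded"
  )
})
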