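test_that("LUT construction validates its inputs and stores metadata", {
  geom <- detector_geometry()
  expect_error(build_lut(c(1, 0.5, 2), geometry = geom), "increasing")
  expect_error(build_lut(c(0.5, 1, 2), geometry = geom), "4 nodes")
  expect_error(build_lut(c(0.5, 1, 2, 3), geometry = geom, n_photons = 100), "1e4")
  lut <- build_lut(c(0.5, 1, 2, 3), geometry = geom, n_photons = 1e4, seed = 44)
  expect_equal(nrow(lut$table), 4)
  expect_equal(ncol(lut$table), 3)
  expect_true(all(lut$table >= 0 & lut$table <= 1))
  expect_equal(lut$mu_a, 0.001)
  lut2 <- build_lut(c(0.5, 1, 2, 3), geometry = geom, n_photons = 1e4, seed = 44)
  expect_identical(lut$table, lut2$table)
})

test_that("interpolation is exact at grid nodes and log-linear between", {
  lut <- test_lut()
  for (i in c(1, 7, 20)) {
    expect_equal(lut_interpolate(lut, lut$grid[i]), unname(lut$table[i, ]))
  }
  # midpoint in log space = geometric mean of the bracketing rows
  m <- sqrt(lut$grid[5] * lut$grid[6])
  expect_equal(lut_interpolate(lut, m),
               unname(sqrt(lut$table[5, ] * lut$table[6, ])), tolerance = 1e-12)
})

test_that("reflectance at the shortest ring increases with scattering", {
  lut <- test_lut()
  r1 <- lut$table[, 1]
  # coarse trend: clearly monotone on a subsampled grid where the signal
  # difference dominates Monte Carlo noise, and strongly rank-correlated overall
  expect_true(all(diff(r1[seq(1, 20, by = 4)]) > 0))
  expect_gt(cor(seq_along(r1), r1, method = "spearman"), 0.95)
})

test_that("decay fits reproduce exact exponential profiles", {
  geom <- detector_geometry()
  prof <- profile_from(exp(-0.002 * geom$ring_centers_um), geom)
  fit <- fit_decay(prof)
  expect_equal(fit$k_per_um, 0.002, tolerance = 1e-12)
  expect_lt(fit$residual_norm, 1e-12)
  flat <- fit_decay(profile_from(rep(0.3, 3), geom))
  expect_equal(flat$k_per_um, 0, tolerance = 1e-12)
  two <- detector_geometry(c(1100, 1550))
  fit2 <- fit_decay(profile_from(c(0.02, 0.005), two))
  expect_lt(fit2$residual_norm, 1e-12)
  expect_error(fit_decay(profile_from(c(0.1, 0, 0.01), geom)), "1550")
})

test_that("self-inversion of every LUT row is exact with zero residual", {
  lut <- test_lut()
  for (i in seq_along(lut$grid)) {
    prof <- profile_from(lut$table[i, ], lut$geometry)
    inv <- invert_mus_prime(prof, lut)
    expect_equal(inv$mus_prime, lut$grid[i])
    expect_equal(inv$residual, 0)
  }
})

test_that("closed-loop recovery of an off-grid scattering value is within 10%", {
  lut <- test_lut()
  fwd <- simulate_reflectance(optical_properties(0.001, 1.0), lut$geometry,
                              1e5, seed = 202)
  inv <- invert_mus_prime(profile_from(fwd$reflectance, lut$geometry), lut)
  expect_lt(abs(inv$mus_prime - 1.0), 0.10)
  expect_false(inv$boundary_flag)
})

test_that("inversion is sensitive to absolute calibration", {
  lut <- test_lut()
  base <- profile_from(lut$table[10, ], lut$geometry)
  scaled <- profile_from(2 * lut$table[10, ], lut$geometry)
  i1 <- invert_mus_prime(base, lut)
  i2 <- invert_mus_prime(scaled, lut)
  expect_false(isTRUE(all.equal(i1$mus_prime, i2$mus_prime)))
})

test_that("geometry mismatches are rejected with both geometries listed", {
  lut <- test_lut()
  other <- detector_geometry(c(900, 1300, 1700))
  prof <- profile_from(c(0.02, 0.01, 0.005), other)
  expect_error(invert_mus_prime(prof, lut), "900/1300/1700")
  expect_error(invert_mus_prime(prof, lut), "1100/1550/2000")
})

test_that("LUT persists to CSV + JSON and reloads identically", {
  lut <- test_lut()
  prefix <- withr::local_tempfile()
  write_lut(lut, prefix)
  back <- read_lut(prefix)
  expect_equal(back$grid, lut$grid)
  expect_equal(unname(back$table), unname(lut$table))
  expect_equal(back$mu_a, lut$mu_a)
  expect_equal(back$geometry$ring_centers_um, lut$geometry$ring_centers_um)
  # a reloaded LUT inverts exactly like the original
  prof <- profile_from(lut$table[8, ], lut$geometry)
  expect_equal(invert_mus_prime(prof, back)$mus_prime,
               invert_mus_prime(prof, lut)$mus_prime)
})
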