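test_that("Henyey-Greenstein inverse-CDF sampling matches the closed form", {
  expect_equal(sample_hg_cosine(0, 0.75), 0.5)
  # closed form at g = 0.9, u = 0.5: (1 + g^2 - ((1-g^2)/(1-g+2gu))^2) / (2g)
  expect_equal(sample_hg_cosine(0.9, 0.5),
               (1 + 0.81 - (0.19 / 1.0)^2) / 1.8, tolerance = 1e-12)
  set.seed(31)
  u <- runif(1e4)
  ct <- sample_hg_cosine(0.6, u)
  expect_true(all(ct >= -1 & ct <= 1))
  expect_error(sample_hg_cosine(1.0, 0.5), "abs")
})

test_that("sampled deflection cosines average to g", {
  set.seed(77)
  ct <- sample_hg_cosine(0.7, runif(1e5))
  se <- sd(ct) / sqrt(length(ct))
  expect_lt(abs(mean(ct) - 0.7), 3 * se)
})

test_that("isotropic sampling passes a uniformity goodness-of-fit test", {
  set.seed(55)
  ct <- sample_hg_cosine(0, runif(1e5))
  counts <- table(cut(ct, breaks = seq(-1, 1, length.out = 21)))
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.01)
})

test_that("Fresnel reflection covers matched, normal-incidence and total-internal cases", {
  expect_equal(fresnel_reflectance(1.34, 1.34, 0.5), 0)
  expect_equal(fresnel_reflectance(1.0, 1.34, 1.0), ((1 - 1.34) / (1 + 1.34))^2,
               tolerance = 1e-12)
  # beyond the critical angle going dense -> rare
  cos_beyond <- cos(asin(1 / 1.34) + 0.05)
  expect_equal(fresnel_reflectance(1.34, 1.0, cos_beyond), 1)
  set.seed(8)
  r <- fresnel_reflectance(1.34, 1.0, runif(100, 0.01, 1))
  expect_true(all(r >= 0 & r <= 1))
})

test_that("every simulation conserves energy to 1e-6 relative", {
  geom <- detector_geometry()
  cases <- list(
    c(0.001, 0.5, 0.9), c(0.01, 1, 0.9), c(0.1, 3, 0.5), c(0.001, 0.1, 0)
  )
  for (cs in cases) {
    props <- optical_properties(cs[1], cs[2], g = cs[3])
    tally <- photon_tally(simulate_reflectance(props, geom, 2e4, seed = 17))
    total <- tally$specular + tally$ring_total + tally$escaped_outside + tally$absorbed
    expect_lt(abs(total - tally$launched) / tally$launched, 1e-6)
  }
})

test_that("a near-perfect absorber returns essentially nothing", {
  props <- optical_properties(1e6, 1, g = 0.9)
  prof <- simulate_reflectance(props, detector_geometry(), 1e4, seed = 3)
  expect_true(all(prof$reflectance < 1e-4))
})

test_that("identical seed and inputs reproduce the profile bitwise", {
  props <- optical_properties(0.001, 1.2)
  a <- simulate_reflectance(props, detector_geometry(), 2e4, seed = 9)
  b <- simulate_reflectance(props, detector_geometry(), 2e4, seed = 9)
  expect_identical(a$reflectance, b$reflectance)
  expect_identical(photon_tally(a), photon_tally(b))
  c <- simulate_reflectance(props, detector_geometry(), 2e4, seed = 10)
  expect_false(identical(a$reflectance, c$reflectance))
})

test_that("similarity relation holds: matched mus' gives matched reflectance in the diffusive regime", {
  # mus' = 1 mm^-1 both ways: transport mfp = 1 mm. Residual anisotropy
  # effects decay with distance (~18% at 2 mfp, ~11% at 4); the matched-mus'
  # equivalence holds to better than 15% from ~4 transport mfp outward.
  geom <- detector_geometry(c(4000, 5000), 400, 5500)
  iso <- simulate_reflectance(optical_properties(0.01, 1, g = 0), geom, 3e5, seed = 21)
  ani <- simulate_reflectance(optical_properties(0.01, 1, g = 0.9), geom, 3e5, seed = 22)
  expect_true(all(abs(ani$reflectance / iso$reflectance - 1) < 0.15))
})

test_that("simulated reflectance tracks the diffusion-dipole closed form", {
  geom <- detector_geometry(c(2000, 3500, 5000), 400, 5500)
  props <- optical_properties(0.01, 1, g = 0.9)
  mc <- reflectance_per_area(simulate_reflectance(props, geom, 3e5, seed = 12))
  ref <- diffusion_ring_average(geom, 0.01, 1, n_rel = 1.34)
  expect_true(all(abs(mc$reflectance_per_mm2 / ref$reflectance_per_mm2 - 1) < 0.15))
})

test_that("geometry validation rejects malformed ring layouts", {
  expect_error(detector_geometry(c(2000, 1500)), "increasing")
  expect_error(detector_geometry(c(1000, 1100), ring_width_um = 300), "overlap")
  expect_error(detector_geometry(50, ring_width_um = 200), "below radius 0")
})
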