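test_that("exactly three presets exist, one per age label", {
  p <- age_presets()
  expect_setequal(p$label, c("newborn", "young_adult", "old_adult"))
  expect_equal(nrow(p), 3)
  expect_equal(anyDuplicated(p$label), 0L)
})

test_that("preset values encode the published age contrasts", {
  y <- age_preset("young_adult")
  o <- age_preset("old_adult")
  n <- age_preset("newborn")
  # gelation: young plateau above old; newborn never plateaus
  expect_equal(y$kinetics_plateau, 0.67)
  expect_equal(o$kinetics_plateau, 0.38)
  expect_gt(y$kinetics_plateau, o$kinetics_plateau)
  expect_false(n$kinetics_reaches_plateau)
  # AGE fluorescence: old = 1.4 x young, newborn = young
  expect_equal(o$fluorescence_mean / y$fluorescence_mean, 1.4)
  expect_equal(n$fluorescence_mean, y$fluorescence_mean)
  # fiber morphometry: young has most fibers, newborn/old longer and thicker
  expect_gt(y$fiber_count, n$fiber_count)
  expect_gt(y$fiber_count, o$fiber_count)
  expect_gt(n$fiber_length_mean, y$fiber_length_mean)
  expect_gt(o$fiber_length_mean, y$fiber_length_mean)
  expect_gt(n$fiber_thickness_mean, y$fiber_thickness_mean)
  expect_gt(o$fiber_thickness_mean, y$fiber_thickness_mean)
  # Amide I conformation marker
  expect_equal(n$amide_I_center, 1656)
  expect_equal(y$amide_I_center, 1632)
  expect_equal(o$amide_I_center, 1632)
  # carbohydrate ratio increases with age
  ry <- y$band_amplitudes[[1]][["1032"]] / y$band_amplitudes[[1]][["1082"]]
  ro <- o$band_amplitudes[[1]][["1032"]] / o$band_amplitudes[[1]][["1082"]]
  expect_gt(ro, ry)
})

test_that("reduced scattering ordering young > newborn > old holds across 550-900 nm", {
  wl <- seq(550, 900, by = 10)
  m <- lapply(c("young_adult", "newborn", "old_adult"),
              function(a) preset_mus_prime(age_preset(a), wl)$mus_prime)
  expect_true(all(m[[1]] > m[[2]]))
  expect_true(all(m[[2]] > m[[3]]))
})

test_that("unknown age labels are rejected with the valid labels named", {
  expect_error(age_preset("toddler"), "newborn.*young_adult.*old_adult")
  expect_error(age_preset(1), "valid labels")
})

test_that("fluorescence generator reproduces the preset contrasts exactly at zero CV", {
  o <- generate_fluorescence(age_preset("old_adult"), 1, cv = 0)
  y <- generate_fluorescence(age_preset("young_adult"), 1, cv = 0)
  n <- generate_fluorescence(age_preset("newborn"), 1, cv = 0)
  expect_equal(o$fluorescence_au / y$fluorescence_au, 1.4)
  expect_equal(n$fluorescence_au, y$fluorescence_au)
  r <- generate_fluorescence(age_preset("newborn"), 3, cv = 0.05, seed = 7)
  expect_equal(nrow(r), 3)
  expect_error(generate_fluorescence(age_preset("newborn"), 3, cv = -1), "cv")
})

test_that("every generated dataset carries a ground-truth bundle that round-trips through JSON", {
  curve <- generate_kinetics(age_preset("young_adult"), seed = 4)
  gt <- ground_truth(curve)
  expect_equal(gt$preset_label, "young_adult")
  expect_equal(gt$tau_max, 0.67)
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(curve, path)
  back <- read_ground_truth(path)
  expect_equal(back$preset_label, gt$preset_label)
  expect_equal(back$tau_max, gt$tau_max)
  expect_equal(back$rate, gt$rate)
  expect_equal(back$t_half, gt$t_half)

  fib <- generate_fiber_stack(age_preset("old_adult"), c(192, 192, 9),
                              seed = 5, n_fibers = 2)
  gt2 <- ground_truth(fib$stack)
  write_ground_truth(fib$stack, path)
  back2 <- read_ground_truth(path)
  expect_equal(back2$fiber_count, gt2$fiber_count)
  expect_equal(back2$lengths_um, gt2$lengths_um)
  expect_equal(back2$thicknesses_um, gt2$thicknesses_um)
})

test_that("seed substreams are label-separated and stable", {
  expect_equal(split_seed(1, "kinetics/newborn"), split_seed(1, "kinetics/newborn"))
  expect_false(split_seed(1, "kinetics/newborn") == split_seed(1, "kinetics/old_adult"))
  expect_false(split_seed(1, "a") == split_seed(2, "a"))
  s <- vapply(sprintf("lut/node%d", 1:50), function(l) split_seed(123, l), integer(1))
  expect_equal(anyDuplicated(s), 0L)
  expect_true(all(s > 0 & s < 2^31))
})
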