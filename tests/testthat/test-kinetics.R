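test_that("absorbance-to-turbidity conversion is the 2.303 linear map", {
  expect_equal(absorbance_to_turbidity(1.0), 2.303)
  expect_equal(absorbance_to_turbidity(0), 0)
  expect_equal(absorbance_to_turbidity(0.5), 1.1515)
  # linearity over random series
  set.seed(42)
  x <- rnorm(50); y <- rnorm(50); a <- 2.5; b <- -0.7
  expect_equal(absorbance_to_turbidity(a * x + b * y),
               a * absorbance_to_turbidity(x) + b * absorbance_to_turbidity(y))
  expect_error(absorbance_to_turbidity(NA_real_))
})

test_that("generated curves have the documented grid, plateau and absorbance channel", {
  for (age in c("newborn", "young_adult", "old_adult")) {
    curve <- generate_kinetics(age_preset(age), 90, 1, noise_sd = 0)
    expect_equal(nrow(curve), 91)
    expect_equal(curve$time_min, 0:90)
    expect_equal(curve$turbidity, 2.303 * curve$absorbance)
  }
  y <- generate_kinetics(age_preset("young_adult"), 90, 1, noise_sd = 0)
  expect_lt(abs(tail(y$turbidity, 1) - 0.67), 0.01)
  n <- generate_kinetics(age_preset("newborn"), 90, 1, noise_sd = 0)
  expect_true(all(diff(n$turbidity) > 0))
  expect_error(generate_kinetics(age_preset("newborn"), noise_sd = -0.1), "noise_sd")
})

test_that("logistic fit recovers noiseless parameters to high relative accuracy", {
  t <- 0:90
  tau <- 0.67 / (1 + exp(-0.35 * (t - 8)))
  fit <- fit_logistic(tibble::tibble(time_min = t, turbidity = tau))
  expect_lt(abs(fit$tau_max - 0.67) / 0.67, 1e-6)
  expect_lt(abs(fit$rate - 0.35) / 0.35, 1e-6)
  expect_lt(abs(fit$t_half - 8) / 8, 1e-6)
  expect_lt(fit$residual, 1e-6)
})

test_that("phase descriptors reproduce the age-specific gelation patterns", {
  y <- fit_logistic(generate_kinetics(age_preset("young_adult"), noise_sd = 0))
  expect_true(y$plateau_reached)
  expect_lte(y$time_to_plateau, 30)
  expect_lte(y$lag_time, 3)
  o <- fit_logistic(generate_kinetics(age_preset("old_adult"), noise_sd = 0))
  expect_true(o$plateau_reached)
  expect_lte(o$lag_time, 1)
  expect_lte(o$time_to_plateau, 10)
  n <- fit_logistic(generate_kinetics(age_preset("newborn"), noise_sd = 0))
  expect_false(n$plateau_reached)
  expect_true(is.na(n$time_to_plateau))
})

test_that("plateau estimation is robust to measurement noise", {
  est <- vapply(1:100, function(i) {
    curve <- generate_kinetics(age_preset("young_adult"), noise_sd = 0.01, seed = i)
    fit_logistic(curve)$tau_max
  }, numeric(1))
  expect_lte(median(abs(est - 0.67)), 0.02)
})

test_that("fit is invariant to uniform time shifts up to the shift in t_half and lag", {
  t <- 0:90
  tau <- 0.67 / (1 + exp(-0.35 * (t - 8)))
  f0 <- fit_logistic(tibble::tibble(time_min = t, turbidity = tau))
  f5 <- fit_logistic(tibble::tibble(time_min = t + 5, turbidity = tau))
  expect_equal(f5$tau_max, f0$tau_max, tolerance = 1e-6)
  expect_equal(f5$rate, f0$rate, tolerance = 1e-6)
  expect_equal(f5$t_half, f0$t_half + 5, tolerance = 1e-6)
  expect_equal(f5$lag_time, f0$lag_time + 5)
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(fit_logistic(tibble::tibble(time_min = 0:5, turbidity = (0:5) / 10)),
               "at least 10")
  expect_error(fit_logistic(tibble::tibble(time_min = 0:20, turbidity = rep(0.4, 21))),
               "constant")
})

test_that("cross-age comparison reports the printed plateau contrast and pattern", {
  fits <- list(
    young_adult = fit_logistic(generate_kinetics(age_preset("young_adult"), noise_sd = 0)),
    old_adult = fit_logistic(generate_kinetics(age_preset("old_adult"), noise_sd = 0))
  )
  cmp <- compare_ages(fits)
  d <- cmp$d_tau_max[cmp$age_a == "young_adult" & cmp$age_b == "old_adult"]
  expect_lt(abs(d - 0.29), 0.02)
  expect_true(attr(cmp, "pattern")$old_faster_lower_plateau)
  same <- compare_ages(list(a = fits$young_adult, b = fits$young_adult))
  expect_equal(same$d_tau_max, 0)
  expect_equal(same$d_lag_time, 0)
})

test_that("tidy and glance expose the fitted parameters", {
  fit <- fit_logistic(generate_kinetics(age_preset("young_adult"), noise_sd = 0))
  td <- tidy(fit)
  expect_setequal(td$term, c("tau_max", "rate", "t_half"))
  g <- glance(fit)
  expect_true(all(c("tau_max", "lag_time", "time_to_plateau", "plateau_reached",
                    "final_turbidity") %in% names(g)))
  expect_equal(g$tau_max, fit$tau_max)
})
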