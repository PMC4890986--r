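#' Generate a synthetic gelation kinetics curve
#'
#' Simulates the turbidity record of an in-vitro fibrillogenesis assay
#' (absorbance at 400 nm sampled on a uniform time grid). For the two adult
#' presets the true curve is the logistic
#' \eqn{\tau(t) = \tau_{max} / (1 + e^{-r(t - t_{1/2})})}; the newborn
#' preset instead follows the slow saturating ramp
#' \eqn{\tau(t) = 0.45\, t / (t + 180)}, still rising at the end of a 90-min
#' record so that no plateau is detected. I.i.d. Gaussian noise of standard
#' deviation `noise_sd` is added to the turbidity; the absorbance channel is
#' `turbidity / 2.303`.
#'
#' @param preset an [age_preset()] row.
#' @param duration record length, min.
#' @param step sampling interval, min.
#' @param noise_sd turbidity noise standard deviation (>= 0).
#' @param seed master seed; the call uses the substream
#'   `"kinetics/<label>"`. `NULL` leaves the RNG state alone.
#' @return a `turbidity_curve` tibble (`time_min`, `absorbance`,
#'   `turbidity`) carrying its [ground_truth()] bundle.
#' @export
generate_kinetics <- function(preset, duration = 90, step = 1,
                              noise_sd = 0, seed = NULL) {
  stopifnot(nrow(preset) == 1, duration > 0, step > 0)
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  t <- seq(0, duration, by = step)
  tau_true <- if (identical(preset$label, "newborn")) {
    preset$kinetics_plateau * t / (t + preset$kinetics_t_half)
  } else {
    logistic_tau(t, preset$kinetics_plateau, preset$kinetics_rate, preset$kinetics_t_half)
  }
  noise <- if (noise_sd > 0) {
    with_substream(seed, paste0("kinetics/", preset$label), rnorm(length(t), 0, noise_sd))
  } else 0
  tau <- tau_true + noise
  out <- tibble(time_min = t, absorbance = tau / 2.303, turbidity = tau)
  class(out) <- c("turbidity_curve", class(out))
  attr(out, "ground_truth") <- new_ground_truth(
    preset,
    model = if (identical(preset$label, "newborn")) "saturating_ramp" else "logistic",
    tau_max = preset$kinetics_plateau,
    rate = preset$kinetics_rate,
    t_half = preset$kinetics_t_half,
    reaches_plateau = preset$kinetics_reaches_plateau,
    noise_sd = noise_sd
  )
  out
}

#' Generate synthetic fluorescent-AGE readings
#'
#' Replicate readings of advanced-glycation-end-product fluorescence
#' (380 nm excitation / 440 nm emission, arbitrary units) drawn from a
#' Gaussian with the preset mean and coefficient of variation `cv`. The
#' presets encode the published contrast: old-adult mean = 1.4 x
#' young-adult, newborn = young-adult.
#'
#' @param preset an [age_preset()] row.
#' @param n_replicates number of independent readings (default 3).
#' @param cv coefficient of variation of the readings (>= 0).
#' @param seed master seed (substream `"fluorescence/<label>"`).
#' @return tibble with `replicate` and `fluorescence_au`, carrying its
#'   ground-truth bundle.
#' @export
generate_fluorescence <- function(preset, n_replicates = 3, cv = 0.05, seed = NULL) {
  stopifnot(nrow(preset) == 1, n_replicates >= 1)
  if (cv < 0) abort("cv must be >= 0")
  m <- preset$fluorescence_mean
  vals <- if (cv > 0) {
    with_substream(seed, paste0("fluorescence/", preset$label),
                   rnorm(n_replicates, m, cv * m))
  } else rep(m, n_replicates)
  out <- tibble(replicate = seq_len(n_replicates), fluorescence_au = vals)
  attr(out, "ground_truth") <- new_ground_truth(preset, fluorescence_mean = m, cv = cv)
  out
}

#' Generate a synthetic ATR-FTIR spectrum
#'
#' Sum of Gaussian bands at 1032 and 1082 cm\eqn{^{-1}} (width 10
#' cm\eqn{^{-1}}) and at the preset's Amide I center (width 12
#' cm\eqn{^{-1}}), on a gently sloping linear baseline, evaluated on the
#' inclusive descending wavenumber grid `wn_max, wn_max - wn_step, ...,
#' wn_min`, plus i.i.d. Gaussian noise.
#'
#' @param preset an [age_preset()] row.
#' @param wn_min,wn_max wavenumber range, cm^-1 (defaults 750-4000).
#' @param wn_step grid step, cm^-1 (default 2, the acquisition resolution).
#' @param noise_sd absorbance noise standard deviation.
#' @param seed master seed (substream `"ftir/<label>"`).
#' @return an `ftir_spectrum` tibble (`wavenumber`, `absorbance`) with its
#'   ground-truth bundle; not yet preprocessed (see [preprocess_spectrum()]).
#' @export
generate_ftir_spectrum <- function(preset, wn_min = 750, wn_max = 4000,
                                   wn_step = 2, noise_sd = 0, seed = NULL) {
  stopifnot(nrow(preset) == 1, wn_min < wn_max, wn_step > 0)
  wn <- seq(wn_max, wn_min, by = -wn_step)
  amps <- preset$band_amplitudes[[1]]
  centers <- c(1032, 1082, preset$amide_I_center)
  widths <- c(10, 10, 12)
  heights <- c(amps[["1032"]], amps[["1082"]], amps[["amide_I"]])
  absorb <- 0.02 + 1e-5 * (wn - wn_min)  # linear instrument baseline
  for (i in seq_along(centers)) {
    absorb <- absorb + heights[i] * exp(-(wn - centers[i])^2 / (2 * widths[i]^2))
  }
  if (noise_sd > 0) {
    absorb <- absorb + with_substream(seed, paste0("ftir/", preset$label),
                                      rnorm(length(wn), 0, noise_sd))
  }
  out <- tibble(wavenumber = wn, absorbance = absorb)
  class(out) <- c("ftir_spectrum", class(out))
  attr(out, "preprocessing") <- c(baseline_corrected = FALSE,
                                  offset_corrected = FALSE,
                                  vector_normalized = FALSE)
  attr(out, "ground_truth") <- new_ground_truth(
    preset,
    band_centers = centers, band_widths = widths, band_heights = heights,
    amide_I_center = preset$amide_I_center,
    ratio_1032_1082 = heights[1] / heights[2],
    noise_sd = noise_sd
  )
  out
}

#' Generate a synthetic multi-distance, multi-wavelength reflectance profile
#'
#' For each wavelength, evaluates the preset's scattering power law
#' \eqn{\mu_s'(\lambda) = a(\lambda/550)^{-b}}, runs the Monte Carlo forward
#' model (or interpolates a precomputed look-up table if one is supplied) at
#' that \eqn{\mu_s'} with the fixed near-zero absorption, and applies
#' multiplicative Gaussian noise of coefficient of variation `noise_cv`.
#'
#' @param preset an [age_preset()] row.
#' @param wavelengths wavelengths, nm, within 450-1000 nm.
#' @param geometry a [detector_geometry()].
#' @param n_photons photons per wavelength for the forward simulation.
#' @param noise_cv multiplicative noise coefficient of variation.
#' @param seed master seed (substreams `"drs/<label>/<lambda>"`).
#' @param lut optional [build_lut()] result: interpolate instead of
#'   simulating (much faster; geometry must match).
#' @param mu_a fixed absorption, mm^-1 (default 0.001, "close to zero").
#' @return a `reflectance_profile` tibble (`wavelength_nm`, `distance_um`,
#'   `reflectance`) with geometry and ground truth attached.
#' @export
generate_drs_measurement <- function(preset, wavelengths = c(550, 650, 750, 850),
                                     geometry = detector_geometry(),
                                     n_photons = 5e4, noise_cv = 0,
                                     seed = 1L, lut = NULL, mu_a = 0.001) {
  stopifnot(nrow(preset) == 1, length(geometry$ring_centers_um) >= 2)
  if (any(wavelengths < 450 | wavelengths > 1000)) {
    abort("wavelengths must lie within the supported 450-1000 nm band")
  }
  if (!is.null(lut) && !geometry_equal(lut$geometry, geometry)) {
    abort("supplied LUT geometry does not match the requested geometry")
  }
  musp <- preset_mus_prime(preset, wavelengths)$mus_prime
  rows <- purrr::map2_dfr(wavelengths, musp, function(wl, m) {
    r <- if (is.null(lut)) {
      props <- optical_properties(mu_a = mu_a, mu_s_prime = m)
      simulate_reflectance(props, geometry, n_photons,
                           seed = split_seed(seed %||% 1L, paste0("drs/", preset$label, "/", wl)))$reflectance
    } else {
      lut_interpolate(lut, m)
    }
    if (noise_cv > 0) {
      f <- with_substream(seed, paste0("drsnoise/", preset$label, "/", wl),
                          rnorm(length(r), 1, noise_cv))
      r <- r * f
    }
    tibble(wavelength_nm = wl, distance_um = geometry$ring_centers_um, reflectance = r)
  })
  attr(rows, "geometry") <- geometry
  attr(rows, "mu_a") <- mu_a
  attr(rows, "n_photons") <- n_photons
  attr(rows, "seed") <- seed
  attr(rows, "ground_truth") <- new_ground_truth(
    preset,
    wavelengths = wavelengths, mus_prime = musp,
    mus_prime_amplitude = preset$mus_prime_amplitude,
    mus_prime_power = preset$mus_prime_power,
    mu_a = mu_a, noise_cv = noise_cv
  )
  class(rows) <- c("reflectance_profile", class(rows))
  rows
}
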