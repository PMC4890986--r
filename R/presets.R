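#' Age presets for synthetic collagen matrices
#'
#' The package encodes three donor-age conditions for rat-tail type I collagen
#' — `newborn`, `young_adult` and `old_adult` — as parameter bundles driving
#' every synthetic-data generator. The presets reproduce the qualitative and
#' quantitative contrasts reported for different-age collagen 3D matrices:
#'
#' * gelation kinetics: young-adult plateau turbidity 0.67 versus old-adult
#'   0.38; the old-adult gel sets faster (no lag phase, plateau by ~10 min);
#'   the newborn collagen polymerizes so slowly that no plateau is reached
#'   within 90 min (modelled as a saturating ramp, see
#'   [generate_kinetics()]);
#' * fluorescent advanced glycation end products (AGEs): old-adult signal is
#'   40% above young-adult; newborn equals young-adult;
#' * reduced scattering: \eqn{\mu_s'(\lambda) = a (\lambda/550)^{-b}} with
#'   amplitude ordering young-adult > newborn > old-adult over 550–900 nm;
#' * fiber morphometry: young-adult matrices have the most fibers; newborn
#'   and old-adult fibers are longer and thicker;
#' * ATR-FTIR: Amide I maximum at 1656 cm\eqn{^{-1}} (newborn) versus
#'   1632 cm\eqn{^{-1}} (both adults); carbohydrate-to-protein intensity
#'   ratio I1032/I1082 increasing with age.
#'
#' Quantities not pinned down by published values (kinetic rates, fiber
#' counts and dimensions, scattering amplitudes, band amplitudes) are package
#' defaults chosen inside physiologically plausible ranges; see the methods
#' vignette for the rationale behind each.
#'
#' @param label one of `"newborn"`, `"young_adult"`, `"old_adult"`.
#' @return `age_preset()` returns a one-row tibble with class `age_preset`;
#'   `age_presets()` returns all three presets as a three-row tibble.
#'   Columns: `label`, `kinetics_plateau`, `kinetics_rate` (min^-1),
#'   `kinetics_t_half` (min), `kinetics_reaches_plateau`,
#'   `fluorescence_mean` (a.u.), `mus_prime_amplitude` (mm^-1 at 550 nm),
#'   `mus_prime_power`, `fiber_count`, `fiber_length_mean` (um),
#'   `fiber_thickness_mean` (um), `amide_I_center` (cm^-1), and the
#'   list-column `band_amplitudes` (named amplitudes for the 1032, 1082 and
#'   Amide I bands).
#' @examples
#' age_preset("young_adult")$kinetics_plateau   # 0.67
#' age_presets()
#' @export
age_preset <- function(label) {
  valid <- c("newborn", "young_adult", "old_adult")
  if (!is.character(label) || length(label) != 1 || !label %in% valid) {
    abort(paste0(
      "unknown age preset ", deparse(label),
      "; valid labels are: ", paste(valid, collapse = ", ")
    ))
  }
  dplyr::filter(age_presets(), .data$label == .env$label)
}

#' @rdname age_preset
#' @export
age_presets <- function() {
  out <- tibble(
    label = c("newborn", "young_adult", "old_adult"),
    # newborn gels as a slow saturating ramp tau(t) = 0.45 t / (t + 180):
    # plateau field holds the ramp asymptote, t_half its half-saturation time,
    # rate is undefined (no exponential phase within the observation window).
    kinetics_plateau = c(0.45, 0.67, 0.38),
    kinetics_rate = c(NA_real_, 0.35, 0.80),
    kinetics_t_half = c(180, 8, 3),
    kinetics_reaches_plateau = c(FALSE, TRUE, TRUE),
    fluorescence_mean = c(100, 100, 140),
    mus_prime_amplitude = c(0.8, 1.2, 0.4),
    mus_prime_power = c(1.2, 1.2, 1.2),
    fiber_count = c(25L, 60L, 30L),
    fiber_length_mean = c(30, 18, 26),
    fiber_thickness_mean = c(1.4, 0.8, 1.2),
    amide_I_center = c(1656, 1632, 1632),
    band_amplitudes = list(
      c(`1032` = 0.270, `1082` = 0.300, amide_I = 1.0),
      c(`1032` = 0.285, `1082` = 0.300, amide_I = 1.0),
      c(`1032` = 0.390, `1082` = 0.300, amide_I = 1.0)
    )
  )
  class(out) <- c("age_preset", class(out))
  out
}

#' Reduced scattering spectrum of a preset
#'
#' Evaluates the scattering power law \eqn{\mu_s'(\lambda) = a
#' (\lambda/550)^{-b}} encoded in a preset.
#'
#' @param preset an [age_preset()] row.
#' @param wavelengths wavelengths in nm.
#' @return tibble with `wavelength_nm` and `mus_prime` (mm^-1).
#' @export
preset_mus_prime <- function(preset, wavelengths) {
  stopifnot(nrow(preset) == 1)
  tibble(
    wavelength_nm = wavelengths,
    mus_prime = preset$mus_prime_amplitude * (wavelengths / 550)^(-preset$mus_prime_power)
  )
}

#' Ground-truth bundle attached to generated datasets
#'
#' Every synthetic dataset carries the true parameter values that produced it,
#' so downstream estimates can be scored against a known answer. The bundle is
#' a plain list (`preset_label` plus per-modality truth) stored in the
#' `"ground_truth"` attribute; it serializes losslessly to JSON via
#' [write_ground_truth()].
#'
#' @param x a generated dataset.
#' @return the ground-truth list, or `NULL` if absent.
#' @export
ground_truth <- function(x) attr(x, "ground_truth", exact = TRUE)

new_ground_truth <- function(preset, ...) {
  c(list(preset_label = preset$label), list(...))
}

#' @rdname ground_truth
#' @param path file path for the JSON document.
#' @export
write_ground_truth <- function(x, path) {
  gt <- if (!is.data.frame(x) && is.list(x) && !is.null(x[["preset_label"]])) {
    x
  } else {
    ground_truth(x)
  }
  if (is.null(gt)) abort("no ground truth attached to this object")
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
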