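# shared fixtures, built lazily and cached for the whole test session

.fixtures <- new.env(parent = emptyenv())

# a small but honest LUT shared by the inversion tests (20 log-spaced nodes,
# 2e4 photons per node): ~25 s to build, reused everywhere
test_lut <- function() {
  if (is.null(.fixtures$lut)) {
    .fixtures$lut <- build_lut(default_mus_grid(20), n_photons = 2e4,
                               geometry = detector_geometry(), seed = 101)
  }
  .fixtures$lut
}

# single-wavelength profile tibble from a vector of ring reflectances
profile_from <- function(reflectance, geometry = detector_geometry(),
                         wavelength = 600) {
  out <- tibble::tibble(wavelength_nm = wavelength,
                        distance_um = geometry$ring_centers_um,
                        reflectance = reflectance)
  attr(out, "geometry") <- geometry
  class(out) <- c("reflectance_profile", class(out))
  out
}
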