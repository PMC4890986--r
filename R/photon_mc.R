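#' Optical properties of a homogeneous turbid gel
#'
#' @param mu_a absorption coefficient, mm^-1 (>= 0).
#' @param mu_s_prime reduced scattering coefficient \eqn{\mu_s' = \mu_s (1-g)},
#'   mm^-1 (> 0; 0 allowed only for the degenerate transparent case).
#' @param g scattering anisotropy (mean cosine of the single-scattering
#'   deflection), in (-1, 1). Default 0.9, typical of collagenous tissue.
#' @param n_medium refractive index of the gel (default 1.34, hydrated gel).
#' @param n_above refractive index of the half-space above the surface
#'   (default 1.0, air).
#' @return a one-row `optical_properties` tibble.
#' @export
optical_properties <- function(mu_a, mu_s_prime, g = 0.9,
                               n_medium = 1.34, n_above = 1.0) {
  stopifnot(mu_a >= 0, mu_s_prime >= 0, abs(g) < 1, n_medium >= 1, n_above >= 1)
  out <- tibble(mu_a = mu_a, mu_s_prime = mu_s_prime, g = g,
                n_medium = n_medium, n_above = n_above,
                mu_s = mu_s_prime / (1 - g))
  class(out) <- c("optical_properties", class(out))
  out
}

#' Annular detector geometry for spatially-resolved reflectance
#'
#' Models a contact probe with a central illumination fiber and collection
#' fibers at fixed source-detector separations; each separation is scored as
#' an annulus (ring) on the sample surface.
#'
#' @param ring_centers_um strictly increasing source-detector distances, um.
#'   Default 1100, 1550, 2000 um (three distances in the 1100-2000 um range).
#' @param ring_width_um radial width of each scoring annulus, um.
#' @param max_radius_um outer limit of the scored field, um.
#' @return a `detector_geometry` list with ring centers, width, and the
#'   derived inner/outer annulus radii.
#' @export
detector_geometry <- function(ring_centers_um = c(1100, 1550, 2000),
                              ring_width_um = 200,
                              max_radius_um = max(ring_centers_um) + ring_width_um) {
  stopifnot(length(ring_centers_um) >= 1, ring_width_um > 0)
  if (is.unsorted(ring_centers_um, strictly = TRUE)) {
    abort("ring_centers_um must be strictly increasing")
  }
  inner <- ring_centers_um - ring_width_um / 2
  outer <- ring_centers_um + ring_width_um / 2
  if (any(inner < 0)) abort("innermost ring extends below radius 0")
  if (any(head(outer, -1) > tail(inner, -1))) abort("rings overlap")
  if (any(outer > max_radius_um)) abort("rings exceed max_radius_um")
  structure(
    list(ring_centers_um = ring_centers_um, ring_width_um = ring_width_um,
         max_radius_um = max_radius_um, inner_um = inner, outer_um = outer),
    class = "detector_geometry"
  )
}

geometry_equal <- function(a, b) {
  isTRUE(all.equal(a$ring_centers_um, b$ring_centers_um)) &&
    isTRUE(all.equal(a$ring_width_um, b$ring_width_um))
}

#' Sample the Henyey-Greenstein deflection cosine
#'
#' Inverse-CDF sampling of the Henyey-Greenstein phase function: for
#' \eqn{g = 0}, \eqn{\cos\theta = 2u - 1}; otherwise
#' \deqn{\cos\theta = \frac{1}{2g}\left[1 + g^2 -
#'   \left(\frac{1-g^2}{1-g+2gu}\right)^2\right].}
#'
#' @param g anisotropy, |g| < 1.
#' @param u uniform deviates in `[0, 1)`.
#' @return deflection cosines in `[-1, 1]`.
#' @examples
#' sample_hg_cosine(0, 0.75)    # 0.5
#' @export
sample_hg_cosine <- function(g, u) {
  stopifnot(is.numeric(g), length(g) == 1, abs(g) < 1,
            all(u >= 0), all(u < 1))
  hg_cosine_cpp(g, as.numeric(u))
}

#' Unpolarized Fresnel reflection probability
#'
#' Reflection probability for light travelling from index `n1` into `n2` at
#' incidence cosine `cos_incident`; returns 1 beyond the critical angle when
#' `n1 > n2`.
#'
#' @param n1,n2 refractive indices (>= 1).
#' @param cos_incident cosine of the incidence angle, in (0, 1].
#' @return reflection probability in `[0, 1]`.
#' @examples
#' fresnel_reflectance(1.0, 1.34, 1.0)  # ~0.0211, normal incidence
#' @export
fresnel_reflectance <- function(n1, n2, cos_incident) {
  stopifnot(n1 >= 1, n2 >= 1, all(cos_incident > 0), all(cos_incident <= 1))
  vapply(cos_incident, function(ci) fresnel_reflectance_cpp(n1, n2, ci), numeric(1))
}

#' Simulate spatially-resolved diffuse reflectance by Monte Carlo
#'
#' Launches weighted photons into a homogeneous semi-infinite medium at the
#' origin, applies the specular loss at entry, alternates exponential path
#' sampling (step \eqn{s = -\ln u / (\mu_a + \mu_s)}) with implicit-capture
#' weight attenuation (albedo \eqn{\mu_s/(\mu_a+\mu_s)} per interaction),
#' Henyey-Greenstein scattering, and Fresnel-tested escape at the surface;
#' low-weight photons are terminated by Russian roulette (threshold 1e-4,
#' survival probability 0.1, with the roulette weight adjustment balanced in
#' the absorbed tally so every run conserves energy to machine precision).
#' Escaping weight is scored into the annulus containing the exit radius.
#'
#' @param props an [optical_properties()] row.
#' @param geometry a [detector_geometry()].
#' @param n_photons number of photons to launch.
#' @param seed integer seed for the simulation's own (xoshiro256+) RNG;
#'   identical seeds and inputs reproduce the profile bitwise.
#' @return a `mc_reflectance` tibble with `distance_um` and `reflectance`
#'   (escaped weight / launched weight per ring). The full energy tally is in
#'   the `"tally"` attribute (see [photon_tally()]), the inputs in
#'   `"props"`, `"geometry"`, `"n_photons"`, `"seed"`.
#' @export
simulate_reflectance <- function(props, geometry, n_photons, seed = 1L) {
  stopifnot(inherits(geometry, "detector_geometry"), n_photons >= 1)
  res <- mc_simulate_cpp(
    props$mu_a, props$mu_s_prime, props$g, props$n_medium, props$n_above,
    geometry$inner_um / 1000, geometry$outer_um / 1000,
    as.numeric(n_photons), as.numeric(seed)
  )
  out <- tibble(
    distance_um = geometry$ring_centers_um,
    reflectance = res$ring_weight / res$launched
  )
  attr(out, "tally") <- tibble(
    launched = res$launched,
    specular = res$specular,
    ring_total = sum(res$ring_weight),
    escaped_outside = res$escaped_outside,
    absorbed = res$absorbed
  )
  attr(out, "props") <- props
  attr(out, "geometry") <- geometry
  attr(out, "n_photons") <- n_photons
  attr(out, "seed") <- seed
  class(out) <- c("mc_reflectance", class(out))
  out
}

#' Energy tally of a Monte Carlo run
#'
#' @param x a result of [simulate_reflectance()].
#' @return one-row tibble with `launched`, `specular`, `ring_total`,
#'   `escaped_outside`, `absorbed`. The components sum to `launched` to
#'   within 1e-6 relative (energy conservation).
#' @export
photon_tally <- function(x) attr(x, "tally", exact = TRUE)

#' Reflectance per unit area
#'
#' Converts per-ring reflectance (fraction of launched weight) into
#' reflectance per unit surface area (mm^-2) by dividing by each annulus
#' area, the quantity directly comparable to the diffusion closed form
#' [diffusion_reflectance()].
#'
#' @param x a `mc_reflectance` result.
#' @return tibble with `distance_um` and `reflectance_per_mm2`.
#' @export
reflectance_per_area <- function(x) {
  geom <- attr(x, "geometry", exact = TRUE)
  area_mm2 <- pi * ((geom$outer_um / 1000)^2 - (geom$inner_um / 1000)^2)
  tibble(distance_um = x$distance_um,
         reflectance_per_mm2 = x$reflectance / area_mm2)
}
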