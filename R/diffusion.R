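#' Steady-state diffusion-dipole reflectance (closed form)
#'
#' Analytic spatially-resolved diffuse reflectance of a semi-infinite
#' homogeneous medium: the extrapolated-boundary dipole (isotropic source at
#' depth \eqn{z_0 = 1/\mu_t'} and negative image mirrored about \eqn{z =
#' -2z_b}, \eqn{z_b = 2AD}) combined with the partial-current escape
#' function, so that the detected signal mixes the fluence and flux
#' contributions at the surface:
#'
#' \deqn{R(\rho) = \frac{1-R_\phi}{4}\,\phi(\rho) + \frac{1-R_j}{2}\,j(\rho)}
#'
#' with
#' \deqn{\phi(\rho) = \frac{1}{4\pi D}\left[\frac{e^{-\mu_{eff} r_1}}{r_1}
#'   - \frac{e^{-\mu_{eff} r_2}}{r_2}\right]}
#' \deqn{j(\rho) = \frac{1}{4\pi}\left[z_0\left(\mu_{eff}+\frac{1}{r_1}\right)
#'  \frac{e^{-\mu_{eff} r_1}}{r_1^2} + (z_0 + 2 z_b)
#'  \left(\mu_{eff}+\frac{1}{r_2}\right)\frac{e^{-\mu_{eff} r_2}}{r_2^2}\right]}
#'
#' where \eqn{D = 1/(3\mu_t')}, \eqn{\mu_t' = \mu_a + \mu_s'},
#' \eqn{\mu_{eff} = \sqrt{3\mu_a\mu_t'}}, \eqn{r_1^2 = z_0^2 + \rho^2},
#' \eqn{r_2^2 = (z_0+2z_b)^2 + \rho^2}. The boundary moments \eqn{R_\phi}
#' and \eqn{R_j} are hemispheric Fresnel integrals of the relative index,
#' \eqn{R_{eff} = (R_\phi + R_j)/(2 - R_\phi + R_j)} and
#' \eqn{A = (1+R_{eff})/(1-R_{eff})}.
#'
#' This escape-function form tracks Monte Carlo transport considerably
#' better than the flux-only dipole at source-detector distances of a few
#' transport mean free paths; it serves as the independent physics reference
#' for the Monte Carlo forward model and is never used inside the
#' simulation or inversion paths.
#'
#' @param rho_mm radial source-detector distance(s), mm.
#' @param mu_a absorption coefficient, mm^-1.
#' @param mu_s_prime reduced scattering coefficient, mm^-1.
#' @param n_rel relative refractive index medium/above (default 1.34).
#' @return diffuse reflectance per unit area, mm^-2, at each `rho_mm`.
#' @export
diffusion_reflectance <- function(rho_mm, mu_a, mu_s_prime, n_rel = 1.34) {
  stopifnot(mu_a > 0, mu_s_prime > 0, all(rho_mm > 0))
  mu_tp <- mu_a + mu_s_prime
  D <- 1 / (3 * mu_tp)
  mu_eff <- sqrt(3 * mu_a * mu_tp)
  z0 <- 1 / mu_tp
  mom <- boundary_moments(n_rel)
  A <- (1 + mom$r_eff) / (1 - mom$r_eff)
  zb <- 2 * A * D
  r1 <- sqrt(z0^2 + rho_mm^2)
  r2 <- sqrt((z0 + 2 * zb)^2 + rho_mm^2)
  phi <- (exp(-mu_eff * r1) / r1 - exp(-mu_eff * r2) / r2) / (4 * pi * D)
  flux <- (z0 * (mu_eff + 1 / r1) * exp(-mu_eff * r1) / r1^2 +
             (z0 + 2 * zb) * (mu_eff + 1 / r2) * exp(-mu_eff * r2) / r2^2) / (4 * pi)
  (1 - mom$r_phi) / 4 * phi + (1 - mom$r_j) / 2 * flux
}

# hemispheric Fresnel moments of the internal boundary (cached per index)
boundary_moments <- local({
  cache <- list()
  function(n_rel) {
    key <- format(n_rel, digits = 12)
    if (is.null(cache[[key]])) {
      fr <- function(th) vapply(th, function(t) fresnel_reflectance(n_rel, 1, cos(t)),
                                numeric(1))
      r_phi <- stats::integrate(function(th) 2 * sin(th) * cos(th) * fr(th),
                                0, pi / 2, rel.tol = 1e-10)$value
      r_j <- stats::integrate(function(th) 3 * sin(th) * cos(th)^2 * fr(th),
                              0, pi / 2, rel.tol = 1e-10)$value
      cache[[key]] <<- list(
        r_phi = r_phi, r_j = r_j,
        r_eff = (r_phi + r_j) / (2 - r_phi + r_j)
      )
    }
    cache[[key]]
  }
})

#' Diffusion reflectance averaged over an annulus
#'
#' Area-weighted mean of [diffusion_reflectance()] over each scoring annulus
#' of a [detector_geometry()], for like-for-like comparison with the Monte
#' Carlo per-ring estimate (see [reflectance_per_area()]).
#'
#' @param geometry a [detector_geometry()].
#' @inheritParams diffusion_reflectance
#' @return tibble with `distance_um` and `reflectance_per_mm2`.
#' @export
diffusion_ring_average <- function(geometry, mu_a, mu_s_prime, n_rel = 1.34) {
  vals <- vapply(seq_along(geometry$ring_centers_um), function(k) {
    ri <- geometry$inner_um[k] / 1000
    ro <- geometry$outer_um[k] / 1000
    f <- function(r) diffusion_reflectance(r, mu_a, mu_s_prime, n_rel) * 2 * pi * r
    stats::integrate(f, ri, ro, rel.tol = 1e-9)$value / (pi * (ro^2 - ri^2))
  }, numeric(1))
  tibble(distance_um = geometry$ring_centers_um, reflectance_per_mm2 = vals)
}
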