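#' Default reduced-scattering grid for the look-up table
#'
#' 50 log-spaced nodes over 0.1-5 mm^-1, covering the scattering range of
#' soft collagen gels with smooth log-linear interpolation between nodes.
#'
#' @param n number of nodes.
#' @param range grid limits, mm^-1.
#' @return strictly increasing numeric vector.
#' @export
default_mus_grid <- function(n = 50, range = c(0.1, 5)) {
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

#' Build a Monte Carlo reflectance look-up table
#'
#' Runs the photon transport forward model at every node of a reduced
#' scattering grid (absorption held fixed near zero) and stores the per-ring
#' reflectance with full metadata. Each node uses its own deterministic
#' substream of the master seed, so the table is reproducible and
#' node-order independent.
#'
#' @param grid strictly increasing \eqn{\mu_s'} nodes, mm^-1 (>= 4 nodes).
#' @param mu_a fixed absorption, mm^-1 (default 0.001 - "close to zero"
#'   while keeping the transport albedo below one).
#' @param geometry a [detector_geometry()].
#' @param n_photons photons per node (>= 1e4).
#' @param seed master seed.
#' @param g,n_medium,n_above medium optical constants (see
#'   [optical_properties()]).
#' @return a `reflectance_lut` object: `table` (nodes x rings matrix of
#'   reflectance), `grid`, `mu_a`, `geometry`, `n_photons`, `seed`.
#' @export
build_lut <- function(grid = default_mus_grid(), mu_a = 0.001,
                      geometry = detector_geometry(), n_photons = 1e5,
                      seed = 1L, g = 0.9, n_medium = 1.34, n_above = 1.0) {
  if (is.unsorted(grid, strictly = TRUE)) abort("grid must be strictly increasing")
  if (length(grid) < 4) abort("grid needs at least 4 nodes")
  if (n_photons < 1e4) abort("n_photons must be at least 1e4 per node")
  tab <- t(vapply(seq_along(grid), function(i) {
    props <- optical_properties(mu_a = mu_a, mu_s_prime = grid[i], g = g,
                                n_medium = n_medium, n_above = n_above)
    simulate_reflectance(props, geometry, n_photons,
                         seed = split_seed(seed, paste0("lut/node", i)))$reflectance
  }, numeric(length(geometry$ring_centers_um))))
  structure(
    list(table = tab, grid = grid, mu_a = mu_a, geometry = geometry,
         n_photons = n_photons, seed = seed, g = g,
         n_medium = n_medium, n_above = n_above),
    class = "reflectance_lut"
  )
}

#' @export
print.reflectance_lut <- function(x, ...) {
  cat(sprintf("reflectance_lut: %d nodes over %.3g-%.3g mm^-1, %d rings, %g photons/node\n",
              length(x$grid), min(x$grid), max(x$grid),
              length(x$geometry$ring_centers_um), x$n_photons))
  invisible(x)
}

#' Interpolate a look-up table at an off-grid scattering value
#'
#' Log-linear interpolation: log reflectance per ring is linear in log
#' \eqn{\mu_s'} between adjacent nodes. Queries are clipped to the grid
#' range.
#'
#' @param lut a [build_lut()] result.
#' @param mus_prime query value(s), mm^-1.
#' @return for one query, a reflectance vector (one per ring); for several,
#'   a matrix (queries x rings).
#' @export
lut_interpolate <- function(lut, mus_prime) {
  if (any(lut$table <= 0)) {
    abort("LUT contains non-positive reflectance entries; increase n_photons")
  }
  lx <- log(lut$grid)
  q <- log(pmin(pmax(mus_prime, min(lut$grid)), max(lut$grid)))
  out <- vapply(seq_len(ncol(lut$table)), function(k) {
    stats::approx(lx, log(lut$table[, k]), xout = q, rule = 2)$y
  }, numeric(length(q)))
  if (length(q) == 1) exp(as.numeric(out)) else exp(matrix(out, nrow = length(q)))
}

#' Fit the exponential distance decay of a reflectance profile
#'
#' The reflectance signal at a given wavelength decays approximately
#' exponentially with source-detector distance; this fits
#' \eqn{\ln R = c - k\rho} per wavelength by ordinary least squares and
#' reports the decay constant \eqn{k} (um^-1), the intercept and the
#' residual norm.
#'
#' @param profile a `reflectance_profile` tibble (columns `wavelength_nm`,
#'   `distance_um`, `reflectance`), or a single-wavelength `mc_reflectance`.
#' @return tibble with one row per wavelength: `wavelength_nm`, `k_per_um`,
#'   `intercept`, `residual_norm`.
#' @export
fit_decay <- function(profile) {
  if (!"wavelength_nm" %in% names(profile)) {
    profile <- dplyr::mutate(profile, wavelength_nm = NA_real_)
  }
  bad <- profile$reflectance <= 0
  if (any(bad)) {
    abort(paste0("non-positive reflectance at distance(s) ",
                 paste(profile$distance_um[bad], collapse = ", "),
                 " um; the log-linear decay fit is undefined there"))
  }
  profile |>
    dplyr::group_by(.data$wavelength_nm) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 2) abort("need at least 2 distances to fit the decay")
      f <- lm(log(reflectance) ~ distance_um, data = d)
      tibble(k_per_um = -unname(coef(f)[2]),
             intercept = unname(coef(f)[1]),
             residual_norm = sqrt(sum(resid(f)^2)))
    }) |>
    dplyr::ungroup()
}

golden_section <- function(f, lo, hi, tol) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - phi * (b - a); c2 <- a + phi * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 <= f2) { b <- c2; c2 <- c1; f2 <- f1; c1 <- b - phi * (b - a); f1 <- f(c1) }
    else { a <- c1; c1 <- c2; f1 <- f2; c2 <- a + phi * (b - a); f2 <- f(c2) }
  }
  x <- if (f1 <= f2) c1 else c2
  list(x = x, fx = min(f1, f2))
}

#' Invert multi-distance reflectance into a reduced scattering spectrum
#'
#' Per wavelength, finds the \eqn{\mu_s'} that minimizes the sum of squared
#' differences of log reflectance across rings between the measurement and
#' the look-up table (log-linearly interpolated in \eqn{\mu_s'}). The
#' objective is first evaluated at every grid node; the best node's
#' bracketing interval is then refined by golden-section search (tolerance
#' 1e-4 mm^-1). Ties break toward the smaller \eqn{\mu_s'}; estimates at the
#' grid boundary are flagged as unreliable. The log objective equalizes ring
#' weighting across decades of signal; note that it is *not* invariant to a
#' common rescaling of all ring values — absolute calibration of the
#' measurement against the table matters.
#'
#' @param profile a `reflectance_profile` tibble.
#' @param lut a [build_lut()] result; its geometry must match the profile's.
#' @param tol golden-section tolerance, mm^-1.
#' @return a `mus_prime_spectrum` tibble: `wavelength_nm`, `mus_prime`
#'   (mm^-1), `residual` (objective at the optimum), `boundary_flag`.
#' @export
invert_mus_prime <- function(profile, lut, tol = 1e-4) {
  geom <- attr(profile, "geometry", exact = TRUE)
  if (!is.null(geom) && !geometry_equal(geom, lut$geometry)) {
    abort(paste0(
      "profile geometry (rings at ",
      paste(geom$ring_centers_um, collapse = "/"),
      " um) does not match LUT geometry (rings at ",
      paste(lut$geometry$ring_centers_um, collapse = "/"), " um)"
    ))
  }
  if (!"wavelength_nm" %in% names(profile)) {
    profile <- dplyr::mutate(profile, wavelength_nm = NA_real_)
  }
  grid <- lut$grid
  out <- profile |>
    dplyr::group_by(.data$wavelength_nm) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$distance_um)
      if (any(d$reflectance <= 0)) {
        abort("non-positive reflectance in profile; cannot invert in log space")
      }
      lr <- log(d$reflectance)
      obj <- function(m) sum((lr - log(lut_interpolate(lut, m)))^2)
      node_vals <- vapply(grid, obj, numeric(1))
      i <- which.min(node_vals)  # which.min takes the first (smallest) on ties
      lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
      ref <- golden_section(obj, lo, hi, tol)
      if (node_vals[i] <= ref$fx) {
        est <- grid[i]; res <- node_vals[i]
      } else {
        est <- ref$x; res <- ref$fx
      }
      tibble(mus_prime = est, residual = res,
             boundary_flag = est <= grid[1] + tol | est >= grid[length(grid)] - tol)
    }) |>
    dplyr::ungroup()
  class(out) <- c("mus_prime_spectrum", class(out))
  out
}

#' @export
autoplot.mus_prime_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wavelength_nm, y = .data$mus_prime)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "wavelength (nm)", y = expression(mu[s] * "' (mm"^-1 * ")"),
                  title = "Inverted reduced scattering spectrum")
}

#' Persist and reload a look-up table
#'
#' The table itself is written as CSV (`<prefix>.csv`: one row per grid
#' node, columns `mus_prime` then one reflectance column per ring) and the
#' metadata (geometry, absorption, photons, seed) as JSON
#' (`<prefix>.json`).
#'
#' @param lut a [build_lut()] result.
#' @param prefix file path prefix (without extension).
#' @return `write_lut` returns the prefix invisibly; `read_lut` the
#'   reconstructed `reflectance_lut`.
#' @export
write_lut <- function(lut, prefix) {
  df <- as.data.frame(lut$table)
  names(df) <- paste0("R_ring", seq_len(ncol(df)))
  df <- cbind(mus_prime = lut$grid, df)
  write.csv(df, paste0(prefix, ".csv"), row.names = FALSE)
  meta <- list(mu_a = lut$mu_a, n_photons = lut$n_photons, seed = lut$seed,
               g = lut$g, n_medium = lut$n_medium, n_above = lut$n_above,
               ring_centers_um = lut$geometry$ring_centers_um,
               ring_width_um = lut$geometry$ring_width_um)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_lut
#' @export
read_lut <- function(prefix) {
  df <- read.csv(paste0(prefix, ".csv"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  structure(
    list(table = as.matrix(df[, -1, drop = FALSE]), grid = df$mus_prime,
         mu_a = meta$mu_a,
         geometry = detector_geometry(meta$ring_centers_um, meta$ring_width_um),
         n_photons = meta$n_photons, seed = meta$seed, g = meta$g,
         n_medium = meta$n_medium, n_above = meta$n_above),
    class = "reflectance_lut"
  )
}
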