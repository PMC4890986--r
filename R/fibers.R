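#' 3D image stack container
#'
#' A light wrapper around a 3D numeric array of confocal reflectance
#' intensities with its voxel sizes.
#'
#' @param voxels numeric array, dimensions (y, x, z), finite and >= 0.
#' @param pixel_size_xy lateral pixel size, um.
#' @param z_step axial slice spacing, um.
#' @return an `image_stack` object.
#' @export
image_stack <- function(voxels, pixel_size_xy, z_step) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3,
            pixel_size_xy > 0, z_step > 0,
            all(is.finite(voxels)), all(voxels >= 0))
  structure(list(voxels = voxels, pixel_size_xy = pixel_size_xy, z_step = z_step),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack: %d x %d px x %d slices (%.3g um/px, z step %.3g um)\n",
              d[2], d[1], d[3], x$pixel_size_xy, x$z_step))
  invisible(x)
}

# minimum distance between two 2D segments (p1-p2, q1-q2), each a length-2 vec
segment_distance <- function(p1, p2, q1, q2) {
  pt_seg <- function(p, a, b) {
    ab <- b - a
    t <- sum((p - a) * ab) / max(sum(ab^2), .Machine$double.eps)
    t <- min(max(t, 0), 1)
    sqrt(sum((p - (a + t * ab))^2))
  }
  cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]
  # proper intersection check
  d <- function(a, b, c) sign(cross2(b - a, c - a))
  if (d(p1, p2, q1) * d(p1, p2, q2) < 0 && d(q1, q2, p1) * d(q1, q2, p2) < 0) return(0)
  min(pt_seg(p1, q1, q2), pt_seg(p2, q1, q2), pt_seg(q1, p1, p2), pt_seg(q2, p1, p2))
}

#' Generate a synthetic confocal reflectance fiber stack
#'
#' Renders the preset's fiber count as straight 3D tubes with Gaussian
#' radial cross-section (half-maximum at radius = thickness/2) into a
#' volume, adds a constant background, additive Gaussian detector noise and
#' multiplicative speckle on the fiber signal. Fibers lie nearly in the
#' imaging plane (each at a constant depth), are placed non-overlapping by
#' rejection sampling (up to `max_attempts` placements per fiber), and every
#' fiber's centerline, arc length and thickness are recorded in the
#' ground-truth bundle. Per-fiber lengths and thicknesses are drawn around
#' the preset means (15% and 10% CV respectively).
#'
#' @param preset an [age_preset()] row; `fiber_count` may be overridden.
#' @param shape_xyz integer vector (nx, ny, nz); default matches a
#'   512 x 512 field over a 20-um stack at 0.5-um steps (41 slices).
#' @param pixel_size_xy lateral pixel size, um (default 0.26).
#' @param z_step axial step, um (default 0.5).
#' @param seed master seed (substream `"fibers/<label>"`).
#' @param n_fibers optional override of the preset fiber count.
#' @param snr peak-signal-to-noise ratio of the additive noise (default 8).
#' @param max_attempts placement attempts per fiber before giving up.
#' @return list with `stack` (an [image_stack()]) and `truth` (per-fiber
#'   tibble: endpoints in px, depth slice, `length_um`, `thickness_um`);
#'   both carry the ground-truth bundle.
#' @export
generate_fiber_stack <- function(preset, shape_xyz = c(512, 512, 41),
                                 pixel_size_xy = 0.26, z_step = 0.5,
                                 seed = 1L, n_fibers = NULL, snr = 8,
                                 max_attempts = 200) {
  stopifnot(nrow(preset) == 1, all(shape_xyz > 0), pixel_size_xy > 0, z_step > 0)
  nx <- shape_xyz[1]; ny <- shape_xyz[2]; nz <- shape_xyz[3]
  count <- n_fibers %||% preset$fiber_count

  gen <- function() {
    placed <- list()
    if (count > 0) {
      for (i in seq_len(count)) {
        len_um <- max(rnorm(1, preset$fiber_length_mean, 0.15 * preset$fiber_length_mean),
                      0.4 * preset$fiber_length_mean)
        thick_um <- max(rnorm(1, preset$fiber_thickness_mean, 0.10 * preset$fiber_thickness_mean),
                        0.5 * preset$fiber_thickness_mean)
        len_px <- len_um / pixel_size_xy
        r_px <- thick_um / 2 / pixel_size_xy
        ok <- FALSE
        for (att in seq_len(max_attempts)) {
          theta <- runif(1, 0, pi)
          margin <- r_px + 12  # clear of the detector border band
          xlo <- margin + len_px / 2 * abs(cos(theta))
          xhi <- nx - margin - len_px / 2 * abs(cos(theta))
          ylo <- margin + len_px / 2 * abs(sin(theta))
          yhi <- ny - margin - len_px / 2 * abs(sin(theta))
          if (xlo > xhi || ylo > yhi) next  # fiber cannot fit at this angle
          cx <- runif(1, xlo, xhi)
          cy <- runif(1, ylo, yhi)
          p1 <- c(cx - len_px / 2 * cos(theta), cy - len_px / 2 * sin(theta))
          p2 <- c(cx + len_px / 2 * cos(theta), cy + len_px / 2 * sin(theta))
          clear <- TRUE
          for (f in placed) {
            # clearance well beyond the two radii so detection masks of
            # neighboring fibers never touch (merged crossings are a
            # documented limitation of skeleton-based counting)
            need <- r_px + f$r_px + 10
            if (segment_distance(p1, p2, f$p1, f$p2) < need) { clear <- FALSE; break }
          }
          if (clear) {
            zc <- if (nz >= 8) runif(1, 4, nz - 3) else (nz + 1) / 2 + runif(1, -0.5, 0.5)
            placed[[i]] <- list(p1 = p1, p2 = p2, r_px = r_px, z = zc,
                                len_um = len_um, thick_um = thick_um)
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          abort(sprintf(paste0(
            "could not place fiber %d of %d without overlap after %d attempts; ",
            "the volume (%d x %d px) is too crowded for this fiber count"),
            i, count, max_attempts, nx, ny))
        }
      }
    }

    vol <- array(0, dim = c(ny, nx, nz))
    for (f in placed) {
      sigma_um <- f$thick_um / 2 / sqrt(2 * log(2))  # half-max at radius
      sigma_xy <- sigma_um / pixel_size_xy
      pad <- ceiling(4 * sigma_xy)
      xr <- max(1, floor(min(f$p1[1], f$p2[1])) - pad):min(nx, ceiling(max(f$p1[1], f$p2[1])) + pad)
      yr <- max(1, floor(min(f$p1[2], f$p2[2])) - pad):min(ny, ceiling(max(f$p1[2], f$p2[2])) + pad)
      zpad <- ceiling(4 * sigma_um / z_step)
      zr <- max(1, floor(f$z) - zpad):min(nz, ceiling(f$z) + zpad)
      gx <- matrix(rep(xr, each = length(yr)), nrow = length(yr))
      gy <- matrix(rep(yr, times = length(xr)), nrow = length(yr))
      ab <- f$p2 - f$p1
      len2 <- sum(ab^2)
      tpar <- ((gx - f$p1[1]) * ab[1] + (gy - f$p1[2]) * ab[2]) / len2
      tpar <- pmin(pmax(tpar, 0), 1)
      dx <- gx - (f$p1[1] + tpar * ab[1])
      dy <- gy - (f$p1[2] + tpar * ab[2])
      d2_um <- (dx^2 + dy^2) * pixel_size_xy^2
      for (iz in zr) {
        dz_um <- (iz - f$z) * z_step
        vol[yr, xr, iz] <- vol[yr, xr, iz] +
          exp(-(d2_um + dz_um^2) / (2 * sigma_um^2))
      }
    }
    signal <- vol
    vol <- vol * (1 + 0.05 * array(rnorm(length(vol)), dim = dim(vol)))  # speckle
    vol <- vol + 0.02 + array(rnorm(length(vol), 0, 1 / snr), dim = dim(vol))
    vol[vol < 0] <- 0
    list(vol = vol, placed = placed, peak = max(signal, 1))
  }

  res <- with_substream(seed, paste0("fibers/", preset$label), gen())
  truth <- if (length(res$placed)) {
    purrr::map_dfr(seq_along(res$placed), function(i) {
      f <- res$placed[[i]]
      tibble(fiber = i, x0 = f$p1[1], y0 = f$p1[2], x1 = f$p2[1], y1 = f$p2[2],
             z_slice = f$z,
             length_um = sqrt(sum((f$p2 - f$p1)^2)) * pixel_size_xy,
             thickness_um = f$thick_um)
    })
  } else {
    tibble(fiber = integer(), x0 = numeric(), y0 = numeric(),
           x1 = numeric(), y1 = numeric(), z_slice = numeric(),
           length_um = numeric(), thickness_um = numeric())
  }
  stack <- image_stack(res$vol, pixel_size_xy, z_step)
  gt <- new_ground_truth(
    preset,
    fiber_count = count,
    lengths_um = truth$length_um,
    thicknesses_um = truth$thickness_um,
    mean_length_um = if (count > 0) mean(truth$length_um) else NA_real_,
    mean_thickness_um = if (count > 0) mean(truth$thickness_um) else NA_real_
  )
  attr(stack, "ground_truth") <- gt
  attr(truth, "ground_truth") <- gt
  list(stack = stack, truth = truth)
}
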