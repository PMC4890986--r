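#' Maximum intensity projection of a confocal stack
#'
#' Pixelwise maximum over z, the standard rendering for confocal reflectance
#' stacks of fibrillar collagen (e.g. a 20-um stack at 0.5-um steps, 41
#' slices). The lateral pixel size is carried forward.
#'
#' @param stack an [image_stack()].
#' @return a `mip_image`: 2D matrix with `pixel_size_xy` attribute.
#' @export
max_intensity_projection <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  if (d[3] < 1) abort("stack has no slices")
  img <- apply(stack$voxels, c(1, 2), max)
  attr(img, "pixel_size_xy") <- stack$pixel_size_xy
  class(img) <- c("mip_image", class(img))
  img
}

#' Segmentation parameters for fiber extraction
#'
#' @param smooth_sigma pre-smoothing Gaussian sigma, px.
#' @param ridge_scales Hessian ridge-filter scales, px.
#' @param min_object_px minimum object size kept in the mask, px.
#' @param prune_len_px skeleton spurs shorter than this are removed, px.
#' @return a parameter list.
#' @export
segmentation_params <- function(smooth_sigma = 1, ridge_scales = c(1, 2, 4),
                                min_object_px = 30, prune_len_px = 10) {
  list(smooth_sigma = smooth_sigma, ridge_scales = ridge_scales,
       min_object_px = min_object_px, prune_len_px = prune_len_px)
}

shift_mat <- function(m, dy, dx, fill = 0) {
  n <- matrix(fill, nrow(m), ncol(m))
  ys <- max(1, 1 + dy):min(nrow(m), nrow(m) + dy)
  xs <- max(1, 1 + dx):min(ncol(m), ncol(m) + dx)
  n[ys, xs] <- m[ys - dy, xs - dx]
  n
}

# shift with edge replication (for derivative stencils: no border artifacts)
shift_rep <- function(m, dy, dx) {
  yi <- pmin(pmax(seq_len(nrow(m)) - dy, 1), nrow(m))
  xi <- pmin(pmax(seq_len(ncol(m)) - dx, 1), ncol(m))
  m[yi, xi]
}

# multiscale Hessian ridge response for bright curvilinear structures:
# at each scale s the image is smoothed with a Gaussian of sigma s, the
# 2x2 Hessian is formed by central differences, and the response is the
# scale-normalized magnitude of the most negative eigenvalue (bright ridges
# have strongly negative curvature across the ridge). The final response is
# the pixelwise maximum over scales, normalized to [0, 1].
ridge_response <- function(img, scales) {
  resp <- matrix(0, nrow(img), ncol(img))
  for (s in scales) {
    sm <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = s))
    hxx <- shift_rep(sm, 0, 1) - 2 * sm + shift_rep(sm, 0, -1)
    hyy <- shift_rep(sm, 1, 0) - 2 * sm + shift_rep(sm, -1, 0)
    hxy <- (shift_rep(sm, 1, 1) - shift_rep(sm, 1, -1) -
              shift_rep(sm, -1, 1) + shift_rep(sm, -1, -1)) / 4
    lam_min <- ((hxx + hyy) - sqrt((hxx - hyy)^2 + 4 * hxy^2)) / 2
    r <- pmax(0, -lam_min) * s^2
    resp <- pmax(resp, r)
  }
  # Gaussian smoothing padding creates spurious ridges along the image
  # border; blank a band of twice the largest filter scale
  band <- min(2 * max(scales), floor(min(dim(resp)) / 4))
  if (band >= 1) {
    resp[c(seq_len(band), nrow(resp) - seq_len(band) + 1), ] <- 0
    resp[, c(seq_len(band), ncol(resp) - seq_len(band) + 1)] <- 0
  }
  mx <- max(resp)
  if (mx > 0) resp <- resp / mx
  resp
}

# Guo-Hall two-subiteration parallel thinning of a logical matrix
# (chosen over Zhang-Suen, which deletes 2-px diagonal staircases entirely)
thin_skeleton <- function(mask) {
  m <- mask * 1
  repeat {
    changed <- FALSE
    for (phase in 0:1) {
      # neighborhood, image rows increasing downward: p2=N, p3=NE, ... p9=NW
      p2 <- shift_mat(m, 1, 0);  p3 <- shift_mat(m, 1, -1); p4 <- shift_mat(m, 0, -1)
      p5 <- shift_mat(m, -1, -1); p6 <- shift_mat(m, -1, 0); p7 <- shift_mat(m, -1, 1)
      p8 <- shift_mat(m, 0, 1);  p9 <- shift_mat(m, 1, 1)
      C <- (p2 == 0 & (p3 == 1 | p4 == 1)) + (p4 == 0 & (p5 == 1 | p6 == 1)) +
        (p6 == 0 & (p7 == 1 | p8 == 1)) + (p8 == 0 & (p9 == 1 | p2 == 1))
      N1 <- (p9 == 1 | p2 == 1) + (p3 == 1 | p4 == 1) +
        (p5 == 1 | p6 == 1) + (p7 == 1 | p8 == 1)
      N2 <- (p2 == 1 | p3 == 1) + (p4 == 1 | p5 == 1) +
        (p6 == 1 | p7 == 1) + (p8 == 1 | p9 == 1)
      N <- pmin(N1, N2)
      mm <- if (phase == 0) {
        (p6 == 1 | p7 == 1 | p9 == 0) & p8 == 1
      } else {
        (p2 == 1 | p3 == 1 | p5 == 0) & p4 == 1
      }
      cond <- m == 1 & C == 1 & N >= 2 & N <= 3 & !mm
      if (any(cond)) { m[cond] <- 0; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1
}

# 8-connected component labelling by union-find (bwlabel is 4-connected,
# which fragments diagonal skeleton runs)
label8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (!length(idx)) return(lab)
  lab[idx] <- seq_along(idx)
  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (off in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    nb <- shift_mat(lab, off[1], off[2])
    sel <- which(lab > 0 & nb > 0)
    a <- lab[sel]; b <- nb[sel]
    for (k in seq_along(a)) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  lab[idx] <- match(roots, unique(roots))
  lab
}

neighbor_count <- function(sk) {
  s <- sk * 1
  shift_mat(s, -1, -1) + shift_mat(s, -1, 0) + shift_mat(s, -1, 1) +
    shift_mat(s, 0, -1) + shift_mat(s, 0, 1) +
    shift_mat(s, 1, -1) + shift_mat(s, 1, 0) + shift_mat(s, 1, 1)
}

# remove skeleton spurs: walk inward from every endpoint; if a branch point
# is met within max_len steps the walked path is a spur and is deleted
prune_skeleton <- function(sk, max_len) {
  repeat {
    nc <- neighbor_count(sk)
    ends <- which(sk & nc == 1, arr.ind = TRUE)
    if (!nrow(ends)) break
    removed_any <- FALSE
    for (e in seq_len(nrow(ends))) {
      y <- ends[e, 1]; x <- ends[e, 2]
      if (!sk[y, x]) next
      path <- matrix(c(y, x), ncol = 2)
      py <- -1L; px <- -1L
      hit_branch <- FALSE
      for (step in seq_len(max_len)) {
        nb <- NULL
        for (dy in -1:1) for (dx in -1:1) {
          if (dy == 0 && dx == 0) next
          yy <- y + dy; xx <- x + dx
          if (yy < 1 || xx < 1 || yy > nrow(sk) || xx > ncol(sk)) next
          if (sk[yy, xx] && !(yy == py && xx == px)) nb <- rbind(nb, c(yy, xx))
        }
        if (is.null(nb) || nrow(nb) == 0) break       # isolated short segment: keep
        local_nc <- function(yy, xx) {
          ys <- max(1, yy - 1):min(nrow(sk), yy + 1)
          xs <- max(1, xx - 1):min(ncol(sk), xx + 1)
          sum(sk[ys, xs]) - 1
        }
        if (nrow(nb) > 1 || local_nc(nb[1, 1], nb[1, 2]) > 2) {
          hit_branch <- TRUE
          break
        }
        py <- y; px <- x
        y <- nb[1, 1]; x <- nb[1, 2]
        path <- rbind(path, c(y, x))
      }
      if (hit_branch && nrow(path) <= max_len) {
        sk[path] <- FALSE
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
  }
  sk
}

#' Segment fibers in a projected reflectance image
#'
#' Detection pipeline: Gaussian pre-smoothing, multiscale Hessian
#' ridge enhancement (bright curvilinear structures), Otsu global threshold
#' on the normalized ridge response, removal of objects below the minimum
#' size, Guo-Hall skeletonization with pruning of short spurs, and a
#' Euclidean distance map of the mask for thickness readout. Because the
#' ridge response is normalized before thresholding, the segmentation is
#' invariant to rescaling the image intensities by a positive constant.
#' A constant image yields an empty mask, not an error. Crossing fibers
#' merge into a single connected component under this definition.
#'
#' @param image a [max_intensity_projection()] result (or plain 2D matrix).
#' @param params a [segmentation_params()] bundle.
#' @return list with logical `mask`, logical `skeleton`, numeric
#'   `distance_map` (px), and `pixel_size_xy` when known.
#' @export
segment_fibers <- function(image, params = segmentation_params()) {
  img <- unclass(image)
  attr(img, "pixel_size_xy") <- NULL
  stopifnot(is.matrix(img))
  if (max(img) == min(img)) {
    empty <- matrix(FALSE, nrow(img), ncol(img))
    return(list(mask = empty, skeleton = empty,
                distance_map = matrix(0, nrow(img), ncol(img)),
                pixel_size_xy = attr(image, "pixel_size_xy", exact = TRUE)))
  }
  sm <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = params$smooth_sigma))
  resp <- ridge_response(sm, params$ridge_scales)
  thr <- EBImage::otsu(EBImage::Image(resp), range = c(0, 1))
  mask <- resp > thr
  lab <- label8(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= params$min_object_px)
  # hysteresis: a component is a fiber only if it also contains at least one
  # strong-response pixel (second-stage Otsu on the above-threshold response);
  # long weak noise-ridge chains fail this and are dropped
  if (length(keep)) {
    thr2 <- EBImage::otsu(EBImage::Image(resp[resp > thr]), range = c(0, 1))
    comp_max <- vapply(keep, function(k) max(resp[lab == k]), numeric(1))
    keep <- keep[comp_max >= thr2]
  }
  # absolute contrast gate: a real fiber's crest intensity stands far above
  # the background level; in a noise-only image every candidate's crest sits
  # within the noise tail and the image is declared empty
  if (length(keep)) {
    bg_med <- median(sm)
    bg_mad <- stats::mad(sm)
    comp_crest <- vapply(keep, function(k) {
      stats::quantile(sm[lab == k], 0.9, names = FALSE)
    }, numeric(1))
    keep <- keep[comp_crest >= bg_med + 6 * bg_mad]
  }
  mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  skel <- if (any(mask)) prune_skeleton(thin_skeleton(mask), params$prune_len_px)
          else mask
  # free-standing skeleton fragments below the spur length are noise, not
  # fibers, and are removed under the same length cutoff as spurs
  if (any(skel)) {
    ls <- label8(skel)
    small <- which(tabulate(ls[ls > 0]) < params$prune_len_px)
    if (length(small)) skel[ls %in% small] <- FALSE
  }
  # thickness is read from the half-maximum intensity footprint, not the
  # detection mask: per component, the crest intensity is estimated as the
  # median raw intensity along the skeleton and the footprint is the part of
  # the component's mask whose raw intensity exceeds half of it (for a fiber
  # with a Gaussian cross-section the half-maximum footprint has exactly the
  # fiber's nominal width)
  dm <- matrix(0, nrow(mask), ncol(mask))
  if (any(skel)) {
    lab <- label8(mask)
    crest <- vapply(seq_len(max(lab)), function(k) {
      v <- img[skel & lab == k]
      if (length(v)) median(v) else NA_real_
    }, numeric(1))
    fw <- mask & img >= 0.5 * crest[pmax(lab, 1)] & lab > 0
    fw <- fw | skel  # the crest itself always belongs to the footprint
    dm <- as.matrix(EBImage::distmap(EBImage::Image(fw * 1)))
  }
  list(mask = mask, skeleton = skel, distance_map = dm,
       pixel_size_xy = attr(image, "pixel_size_xy", exact = TRUE))
}

#' Measure fiber number, length and thickness from a skeleton
#'
#' Each connected skeleton component (8-connectivity) is one fiber. Per
#' fiber:
#'
#' * **length** — geodesic skeleton length: axial pixel adjacencies count 1,
#'   diagonal adjacencies count \eqn{\sqrt 2} (diagonals that merely cut a
#'   corner of an axial path are skipped), times the pixel size;
#' * **thickness** — twice the mean distance-map value along the fiber's
#'   skeleton, times the pixel size (the distance map is computed on the
#'   half-maximum intensity footprint, see [segment_fibers()]).
#'
#' @param segmentation a [segment_fibers()] result (or list with `skeleton`
#'   and `distance_map`).
#' @param pixel_size_xy lateral pixel size, um; defaults to the value
#'   carried in `segmentation`.
#' @return a `fiber_stats` tibble with one row per fiber (`fiber`,
#'   `length_um`, `thickness_um`); the count and the mean length/thickness
#'   are available via [glance()].
#' @export
measure_fibers <- function(segmentation, pixel_size_xy = NULL) {
  sk <- segmentation$skeleton
  dm <- segmentation$distance_map
  stopifnot(identical(dim(sk), dim(dm)))
  px <- pixel_size_xy %||% segmentation$pixel_size_xy %||% 1
  lab <- label8(sk)
  n <- max(lab)
  if (n == 0) {
    out <- tibble(fiber = integer(), length_um = numeric(), thickness_um = numeric())
    class(out) <- c("fiber_stats", class(out))
    return(out)
  }
  # adjacency counting on the labelled skeleton
  pair_counts <- function(dy, dx) {
    a <- lab
    b <- shift_mat(lab, dy, dx)
    sel <- a > 0 & b == a
    tab <- tabulate(a[sel], nbins = n)
    tab
  }
  ax <- pair_counts(0, 1) + pair_counts(1, 0)
  # a diagonal adjacency is redundant if the two pixels share an axial neighbor
  diag_counts <- function(dy, dx) {
    a <- lab
    b <- shift_mat(lab, dy, dx)
    c1 <- shift_mat(lab, dy, 0)
    c2 <- shift_mat(lab, 0, dx)
    sel <- a > 0 & b == a & c1 != a & c2 != a
    tabulate(a[sel], nbins = n)
  }
  dg <- diag_counts(1, 1) + diag_counts(1, -1)
  lengths_px <- ax + sqrt(2) * dg
  thick_px <- vapply(seq_len(n), function(k) {
    2 * mean(dm[lab == k])
  }, numeric(1))
  out <- tibble(fiber = seq_len(n),
                length_um = lengths_px * px,
                thickness_um = thick_px * px)
  class(out) <- c("fiber_stats", class(out))
  out
}

#' @export
glance.fiber_stats <- function(x, ...) {
  tibble(fiber_count = nrow(x),
         mean_length_um = if (nrow(x)) mean(x$length_um) else NA_real_,
         mean_thickness_um = if (nrow(x)) mean(x$thickness_um) else NA_real_)
}

#' Full morphometry of a confocal stack
#'
#' Convenience wrapper: maximum intensity projection, fiber segmentation
#' and skeleton measurement in one call.
#'
#' @param stack an [image_stack()].
#' @param params a [segmentation_params()] bundle.
#' @return a `fiber_stats` tibble (see [measure_fibers()]).
#' @export
analyze_stack <- function(stack, params = segmentation_params()) {
  mip <- max_intensity_projection(stack)
  seg <- segment_fibers(mip, params)
  measure_fibers(seg, stack$pixel_size_xy)
}
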