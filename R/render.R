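# Geometry primitives and voxel rendering for the synthetic-data generator.
# Compartment layouts are lists of primitives (ellipsoids and capped tubes)
# painted in order into a labelled 3D mask; spots are analytic anisotropic
# 3D Gaussians evaluated on the voxel grid (no FFT convolution).

#' Ellipsoid layout primitive
#' @param label compartment name for the rendered object.
#' @param center_um,semiaxes_um centre and semi-axes in um, `(z, y, x)`.
#' @param channel stack channel the object is rendered into.
#' @param level rendered intensity (photons) inside the object.
#' @export
ellipsoid <- function(label, center_um, semiaxes_um, channel = "marker", level = 500) {
  check_that(all(semiaxes_um > 0), "ellipsoid semi-axes must be positive")
  list(type = "ellipsoid", label = label, center = as.numeric(center_um),
       semiaxes = as.numeric(semiaxes_um), channel = channel, level = level)
}

#' Capped-tube (capsule) layout primitive
#' @param p0_um,p1_um tube endpoints in um, `(z, y, x)`.
#' @param radius_um tube radius in um.
#' @inheritParams ellipsoid
#' @export
tube <- function(label, p0_um, p1_um, radius_um, channel = "marker", level = 500) {
  check_that(radius_um > 0, "tube radius must be positive")
  list(type = "tube", label = label, p0 = as.numeric(p0_um), p1 = as.numeric(p1_um),
       radius = as.numeric(radius_um), channel = channel, level = level)
}

primitive_bbox <- function(prim) {
  if (prim$type == "ellipsoid") {
    rbind(prim$center - prim$semiaxes, prim$center + prim$semiaxes)
  } else {
    rbind(pmin(prim$p0, prim$p1) - prim$radius, pmax(prim$p0, prim$p1) + prim$radius)
  }
}

coord_grids <- function(shape, voxel_size) {
  zc <- (seq_len(shape[1]) - 1) * voxel_size[1]
  yc <- (seq_len(shape[2]) - 1) * voxel_size[2]
  xc <- (seq_len(shape[3]) - 1) * voxel_size[3]
  list(z = array(rep(zc, times = shape[2] * shape[3]), shape),
       y = array(rep(rep(yc, each = shape[1]), times = shape[3]), shape),
       x = array(rep(xc, each = shape[1] * shape[2]), shape))
}

primitive_membership <- function(prim, grids) {
  if (prim$type == "ellipsoid") {
    ((grids$z - prim$center[1]) / prim$semiaxes[1])^2 +
      ((grids$y - prim$center[2]) / prim$semiaxes[2])^2 +
      ((grids$x - prim$center[3]) / prim$semiaxes[3])^2 <= 1
  } else {
    v <- prim$p1 - prim$p0
    len2 <- sum(v^2)
    dz <- grids$z - prim$p0[1]; dy <- grids$y - prim$p0[2]; dx <- grids$x - prim$p0[3]
    t <- if (len2 > 0) pmin(pmax((dz * v[1] + dy * v[2] + dx * v[3]) / len2, 0), 1) else 0
    (dz - t * v[1])^2 + (dy - t * v[2])^2 + (dx - t * v[3])^2 <= prim$radius^2
  }
}

#' Render a compartment layout into a labelled 3D mask
#'
#' Primitives are painted in list order (later primitives overwrite earlier
#' ones, so e.g. a nucleus drawn after its soma carves out its own label).
#' Duplicate labels get a numeric suffix so mask ids map injectively to names.
#'
#' @param layout list of [ellipsoid()] / [tube()] primitives.
#' @param shape integer `(z, y, x)` voxel counts.
#' @param voxel_size um per voxel, `(z, y, x)`.
#' @return a [compartment_mask()].
#' @export
render_compartments <- function(layout, shape, voxel_size) {
  grids <- coord_grids(shape, voxel_size)
  lab <- array(0L, shape)
  nms <- character(length(layout))
  for (i in seq_along(layout)) {
    lab[primitive_membership(layout[[i]], grids)] <- i
    nms[i] <- layout[[i]]$label
  }
  dup <- nms[duplicated(nms)]
  for (d in unique(dup)) {
    at <- which(nms == d)
    nms[at] <- paste0(d, "_", seq_along(at))
  }
  compartment_mask(lab, stats::setNames(nms, seq_along(layout)), voxel_size)
}

# Render a set of Gaussian spots into a 3D array. `spots` needs columns
# z_um, y_um, x_um, amplitude, sigma_ax_um, sigma_lat_um.
render_spots <- function(spots, shape, voxel_size) {
  a <- array(0, shape)
  if (is.null(spots) || nrow(spots) == 0L) return(a)
  for (i in seq_len(nrow(spots))) {
    cz <- spots$z_um[i] / voxel_size[1] + 1
    cy <- spots$y_um[i] / voxel_size[2] + 1
    cx <- spots$x_um[i] / voxel_size[3] + 1
    sz <- spots$sigma_ax_um[i] / voxel_size[1]
    sy <- spots$sigma_lat_um[i] / voxel_size[2]
    sx <- spots$sigma_lat_um[i] / voxel_size[3]
    rz <- max(2L, ceiling(4 * sz)); ry <- max(2L, ceiling(4 * sy)); rx <- max(2L, ceiling(4 * sx))
    iz <- max(1L, floor(cz - rz)):min(shape[1], ceiling(cz + rz))
    iy <- max(1L, floor(cy - ry)):min(shape[2], ceiling(cy + ry))
    ix <- max(1L, floor(cx - rx)):min(shape[3], ceiling(cx + rx))
    gz <- exp(-((iz - cz)^2) / (2 * sz^2))
    gy <- exp(-((iy - cy)^2) / (2 * sy^2))
    gx <- exp(-((ix - cx)^2) / (2 * sx^2))
    a[iz, iy, ix] <- a[iz, iy, ix] + spots$amplitude[i] * (gz %o% gy %o% gx)
  }
  a
}

# Camera noise model: shot noise on signal + baseline, then Gaussian read
# noise. Applied per channel.
apply_noise <- function(clean, baseline, read_sd) {
  n <- length(clean)
  shot <- stats::rpois(n, lambda = pmax(clean + baseline, 0))
  array(shot + stats::rnorm(n, sd = read_sd), dim(clean))
}

# Approximate peak signal-to-noise ratio of a rendered spot under the
# default camera model, and its inverse (amplitude needed for a target SNR).
#' @export
peak_snr <- function(amplitude, baseline = 100, read_sd = 2) {
  amplitude / sqrt(amplitude + baseline + read_sd^2)
}

#' @export
amplitude_for_snr <- function(snr, baseline = 100, read_sd = 2) {
  b <- baseline + read_sd^2
  (snr^2 + snr * sqrt(snr^2 + 4 * b)) / 2
}
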