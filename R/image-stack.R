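#' Multichannel 3D image stack
#'
#' Container for a confocal stack: a named list of 3D voxel arrays (one per
#' channel, dimension order `(z, y, x)`) plus the physical voxel size in
#' micrometres per axis. Voxel coordinates are 0-based with half-open bounds;
#' a physical position in um is `voxel_index * voxel_size`.
#'
#' @param channels named list of 3D numeric arrays, all with identical dims.
#' @param voxel_size numeric length-3, um per voxel along `(z, y, x)`;
#'   strictly positive.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(channels, voxel_size) {
  check_that(is.list(channels) && length(channels) > 0, "channels must be a non-empty named list")
  nm <- names(channels)
  check_that(!is.null(nm) && !anyNA(nm) && !any(nm == "") && !anyDuplicated(nm),
             "channel names must be unique and non-empty")
  dims <- lapply(channels, dim)
  check_that(all(vapply(dims, length, 1L) == 3L), "each channel must be a 3D array")
  check_that(length(unique(lapply(dims, as.integer))) == 1L,
             "all channels must share the same dimensions")
  voxel_size <- as.numeric(voxel_size)
  check_that(length(voxel_size) == 3L && all(is.finite(voxel_size)) && all(voxel_size > 0),
             "voxel_size must be three strictly positive values (z, y, x)")
  structure(list(channels = channels, voxel_size = voxel_size),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<image_stack> %d x %d x %d voxels (z,y,x), voxel %s um, channels: %s\n",
              d[1], d[2], d[3], paste(signif(x$voxel_size, 3), collapse = " x "),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$channels[[1]])

get_channel <- function(stack, channel) {
  if (is.null(channel)) {
    check_that(length(stack$channels) == 1L,
               "stack has several channels; name one", input_error)
    return(stack$channels[[1]])
  }
  check_that(channel %in% names(stack$channels),
             sprintf("channel '%s' not present in stack", channel), input_error)
  stack$channels[[channel]]
}

#' Point-spread-function width model
#'
#' Diffraction-limited spots are modelled as anisotropic 3D Gaussians with a
#' lateral (xy) and an axial (z) standard deviation.
#'
#' @param sigma_lateral,sigma_axial Gaussian sigma in um; axial must be at
#'   least the lateral width.
#' @export
psf_model <- function(sigma_lateral = 0.13, sigma_axial = 0.35) {
  check_that(is.numeric(sigma_lateral) && sigma_lateral > 0, "sigma_lateral must be > 0")
  check_that(is.numeric(sigma_axial) && sigma_axial >= sigma_lateral,
             "sigma_axial must be >= sigma_lateral")
  structure(list(sigma_lateral = as.numeric(sigma_lateral),
                 sigma_axial = as.numeric(sigma_axial)),
            class = "psf_model")
}

# PSF sigma in voxel units, (z, y, x).
psf_sigma_vox <- function(psf, voxel_size) {
  c(psf$sigma_axial / voxel_size[1],
    psf$sigma_lateral / voxel_size[2],
    psf$sigma_lateral / voxel_size[3])
}
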