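# Minimal baseline-TIFF I/O for multichannel 3D stacks.
#
# The stacks written here are classic little-endian TIFFs: one IFD per plane,
# uncompressed 32-bit IEEE float, single strip, plane order z-major then
# channel (Z,C). Stack metadata (shape, voxel size in um, channel names)
# travels as a JSON ImageDescription tag, so files round-trip losslessly and
# are readable by the usual scientific TIFF readers.

TIFF_TYPE_ASCII <- 2L
TIFF_TYPE_SHORT <- 3L
TIFF_TYPE_LONG  <- 4L

#' Write an image stack as a multi-page float TIFF
#'
#' @param stack an [image_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  check_that(inherits(stack, "image_stack"), "stack must be an image_stack", input_error)
  d <- dim(stack)
  nz <- d[1]; ny <- d[2]; nx <- d[3]; nc <- length(stack$channels)
  meta <- list(axes = "ZCYX", shape = c(nz, nc, ny, nx),
               voxel_size_um = stack$voxel_size,
               channel_names = names(stack$channels))
  desc <- jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)
  desc_raw <- c(charToRaw(as.character(desc)), as.raw(0L))
  if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0L))

  plane_bytes <- ny * nx * 4L
  n_planes <- nz * nc
  desc_off <- 8L
  data_off0 <- desc_off + length(desc_raw)
  ifd0 <- data_off0 + n_planes * plane_bytes
  n_tags <- 10L
  ifd_size <- 2L + n_tags * 12L + 4L

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd0), con, size = 4, endian = "little")
  writeBin(desc_raw, con)

  # plane data, z-major then channel
  for (z in seq_len(nz)) for (ch in seq_len(nc)) {
    plane <- stack$channels[[ch]][z, , ]           # ny x nx matrix
    writeBin(as.numeric(t(plane)), con, size = 4, endian = "little")
  }

  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == TIFF_TYPE_SHORT && count == 1L) {
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }

  for (p in seq_len(n_planes)) {
    writeBin(n_tags, con, size = 2, endian = "little")
    entry(256L, TIFF_TYPE_LONG, 1L, nx)                       # ImageWidth
    entry(257L, TIFF_TYPE_LONG, 1L, ny)                       # ImageLength
    entry(258L, TIFF_TYPE_SHORT, 1L, 32L)                     # BitsPerSample
    entry(259L, TIFF_TYPE_SHORT, 1L, 1L)                      # Compression: none
    entry(262L, TIFF_TYPE_SHORT, 1L, 1L)                      # Photometric: min-is-black
    entry(270L, TIFF_TYPE_ASCII, length(desc_raw), desc_off)  # ImageDescription
    entry(273L, TIFF_TYPE_LONG, 1L, data_off0 + (p - 1L) * plane_bytes)
    entry(278L, TIFF_TYPE_LONG, 1L, ny)                       # RowsPerStrip
    entry(279L, TIFF_TYPE_LONG, 1L, plane_bytes)              # StripByteCounts
    entry(339L, TIFF_TYPE_SHORT, 1L, 3L)                      # SampleFormat: float
    nxt <- if (p < n_planes) ifd0 + p * ifd_size else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a multi-page TIFF stack written by [write_stack()]
#'
#' Understands uncompressed single-sample baseline TIFF (float32, uint16 or
#' uint8). If the JSON ImageDescription written by this package is present,
#' voxel size and channel names are restored from it; otherwise the planes
#' are returned as one channel with unit voxel size.
#'
#' @param path TIFF file path.
#' @return an [image_stack()].
#' @export
read_stack <- function(path) {
  check_that(file.exists(path), sprintf("file not found: %s", path), input_error)
  raw <- readBin(path, "raw", file.size(path))
  u16 <- function(off) as.integer(raw[off + 1L]) + 256L * as.integer(raw[off + 2L])
  u32 <- function(off) {
    as.numeric(as.integer(raw[off + 1L])) + 256 * as.integer(raw[off + 2L]) +
      65536 * as.integer(raw[off + 3L]) + 16777216 * as.integer(raw[off + 4L])
  }
  check_that(rawToChar(raw[1:2]) == "II" && u16(2L) == 42L,
             "not a little-endian TIFF", input_error)
  ifd_off <- u32(4L)
  planes <- list(); desc <- NULL
  dims <- NULL
  while (ifd_off != 0) {
    n <- u16(ifd_off)
    tags <- list()
    for (i in seq_len(n)) {
      e <- ifd_off + 2L + (i - 1L) * 12L
      tag <- u16(e); type <- u16(e + 2L); count <- u32(e + 4L)
      val <- if (type == TIFF_TYPE_SHORT && count == 1L) u16(e + 8L) else u32(e + 8L)
      tags[[as.character(tag)]] <- list(type = type, count = count, value = val)
    }
    gettag <- function(tag, default = NULL) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) default else t$value
    }
    nx <- gettag(256L); ny <- gettag(257L)
    bits <- gettag(258L, 1L); comp <- gettag(259L, 1L)
    fmt <- gettag(339L, 1L)
    check_that(comp == 1L, "compressed TIFF not supported", input_error)
    off <- gettag(273L); nbytes <- gettag(279L, nx * ny * bits / 8)
    if (is.null(desc) && !is.null(tags[["270"]])) {
      t <- tags[["270"]]
      dr <- raw[(t$value + 1L):(t$value + t$count)]
      dr <- dr[dr != as.raw(0L)]
      desc <- tryCatch(jsonlite::fromJSON(rawToChar(dr)), error = function(e) NULL)
    }
    npix <- nx * ny
    vals <- if (fmt == 3L && bits == 32L) {
      readBin(raw[(off + 1L):(off + nbytes)], "numeric", npix, size = 4, endian = "little")
    } else if (bits == 16L) {
      readBin(raw[(off + 1L):(off + nbytes)], "integer", npix, size = 2,
              signed = FALSE, endian = "little")
    } else if (bits == 8L) {
      as.integer(raw[(off + 1L):(off + nbytes)])
    } else input_error(sprintf("unsupported TIFF sample layout (bits=%d fmt=%d)", bits, fmt))
    planes[[length(planes) + 1L]] <- matrix(vals, nrow = ny, ncol = nx, byrow = TRUE)
    dims <- c(ny, nx)
    ifd_off <- u32(ifd_off + 2L + n * 12L)
  }
  n_planes <- length(planes)
  if (!is.null(desc) && identical(desc$axes, "ZCYX")) {
    shp <- as.integer(desc$shape)
    nz <- shp[1]; nc <- shp[2]
    check_that(nz * nc == n_planes, "TIFF plane count does not match metadata", input_error)
    chn <- as.character(desc$channel_names)
    channels <- lapply(seq_len(nc), function(ch) {
      a <- array(0, c(nz, dims[1], dims[2]))
      for (z in seq_len(nz)) a[z, , ] <- planes[[(z - 1L) * nc + ch]]
      a
    })
    names(channels) <- chn
    return(image_stack(channels, as.numeric(desc$voxel_size_um)))
  }
  a <- array(0, c(n_planes, dims[1], dims[2]))
  for (z in seq_len(n_planes)) a[z, , ] <- planes[[z]]
  image_stack(list(channel_1 = a), c(1, 1, 1))
}
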