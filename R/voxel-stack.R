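#' Voxel stack: a 3D intensity grid with physical voxel dimensions
#'
#' The unit of image analysis. Intensities are stored as a numeric 3D array
#' indexed \code{[y, x, z]}; voxel sizes are carried as metadata in nm and
#' are not used to resample the grid.
#'
#' @param data numeric 3D array of non-negative intensities, dim
#'   \code{c(ny, nx, nz)}.
#' @param voxel_xy_nm lateral voxel size in nm (> 0).
#' @param voxel_z_nm axial voxel size (z-step) in nm (> 0).
#' @param modality free-text tag, e.g. \code{"confocal"}, \code{"sim"}.
#' @return An object of class \code{voxel_stack}.
#' @export
voxel_stack <- function(data, voxel_xy_nm, voxel_z_nm, modality = "unknown") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (any(dim(data) < 1L)) stop("stack must have at least 1 plane", call. = FALSE)
  stop_if_not_positive(voxel_xy_nm, "voxel_xy_nm")
  stop_if_not_positive(voxel_z_nm, "voxel_z_nm")
  structure(
    list(data = data, voxel_xy_nm = voxel_xy_nm, voxel_z_nm = voxel_z_nm,
         modality = modality),
    class = "voxel_stack"
  )
}

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<voxel_stack> %d x %d x %d voxels (%.0f x %.0f x %.0f nm), modality: %s\n",
    d[1], d[2], d[3], x$voxel_xy_nm, x$voxel_xy_nm, x$voxel_z_nm, x$modality))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.voxel_stack <- function(x) dim(x$data)

as_stack_like <- function(template, data) {
  voxel_stack(data, template$voxel_xy_nm, template$voxel_z_nm,
              template$modality)
}

# ---------------------------------------------------------------------------
# Multi-page TIFF I/O (baseline, uncompressed, 32-bit float, little-endian)
# with a JSON sidecar carrying voxel sizes and modality. No TIFF library is
# available in the target R installation, so the minimal baseline subset is
# implemented here and round-trip tested.
# ---------------------------------------------------------------------------

#' Write a voxel stack to a multi-page TIFF with a JSON sidecar
#'
#' Writes one uncompressed 32-bit-float grayscale page per z-plane and a
#' sidecar \code{<path>.json} with keys \code{voxel_xy_nm}, \code{voxel_z_nm}
#' and \code{modality}.
#'
#' @param stack a \code{\link{voxel_stack}}.
#' @param path output TIFF file path.
#' @return \code{path}, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "voxel_stack"))
  d <- dim(stack$data)
  ny <- d[1]; nx <- d[2]; nz <- d[3]
  con <- file(path, "wb")
  on.exit(close(con))
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  # header: II, magic 42, offset of first IFD (filled after pixel data)
  writeBin(charToRaw("II"), con)
  w2(42L)
  page_bytes <- nx * ny * 4
  first_ifd <- 8L + nz * page_bytes
  w4(first_ifd)
  for (k in seq_len(nz)) {
    # TIFF rows are x-fastest
    writeBin(as.numeric(t(stack$data[, , k])), con, size = 4,
             endian = "little")
  }
  n_entries <- 9L
  ifd_size <- 2L + n_entries * 12L + 4L
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count); w4(value)
  }
  for (k in seq_len(nz)) {
    strip_offset <- 8L + (k - 1L) * page_bytes
    next_ifd <- if (k < nz) first_ifd + k * ifd_size else 0L
    w2(n_entries)
    entry(256L, 3L, 1L, nx)            # ImageWidth
    entry(257L, 3L, 1L, ny)            # ImageLength
    entry(258L, 3L, 1L, 32L)           # BitsPerSample
    entry(259L, 3L, 1L, 1L)            # Compression: none
    entry(262L, 3L, 1L, 1L)            # Photometric: BlackIsZero
    entry(273L, 4L, 1L, strip_offset)  # StripOffsets (single strip)
    entry(278L, 3L, 1L, ny)            # RowsPerStrip
    entry(279L, 4L, 1L, page_bytes)    # StripByteCounts
    entry(339L, 3L, 1L, 3L)            # SampleFormat: IEEE float
    w4(next_ifd)
  }
  jsonlite::write_json(
    list(voxel_xy_nm = stack$voxel_xy_nm, voxel_z_nm = stack$voxel_z_nm,
         modality = stack$modality),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a voxel stack from a multi-page TIFF written by this package
#'
#' Supports the baseline subset written by \code{\link{write_stack_tiff}}
#' (uncompressed little-endian grayscale pages, 32-bit float or 8/16-bit
#' unsigned). Voxel metadata is taken from the \code{<path>.json} sidecar if
#' present.
#'
#' @param path TIFF file path.
#' @return A \code{\link{voxel_stack}}.
#' @export
read_stack_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  u <- function(off, size) {
    # little-endian unsigned integer at 1-based byte offset `off`
    sum(as.integer(raw[off + seq_len(size) - 1L]) * 256^(seq_len(size) - 1L))
  }
  if (rawToChar(raw[1:2]) != "II" || u(3L, 2L) != 42L)
    stop("not a little-endian TIFF file", call. = FALSE)
  ifd <- u(5L, 4L)
  planes <- list()
  while (ifd != 0) {
    n <- u(ifd + 1L, 2L)
    tags <- list()
    for (e in seq_len(n)) {
      off <- ifd + 2L + (e - 1L) * 12L
      tag <- u(off + 1L, 2L)
      type <- u(off + 3L, 2L)
      size <- c(1L, 1L, 2L, 4L, 8L)[type]
      tags[[as.character(tag)]] <- u(off + 9L, min(size, 4L))
    }
    g <- function(t, default = NULL) tags[[as.character(t)]] %||% default
    nx <- g(256L); ny <- g(257L)
    bits <- g(258L, 1L); comp <- g(259L, 1L); fmt <- g(339L, 1L)
    if (comp != 1L) stop("compressed TIFF not supported", call. = FALSE)
    so <- g(273L); sbc <- g(279L, nx * ny * bits / 8)
    bytes <- raw[so + seq_len(sbc)]
    vals <- if (fmt == 3L && bits == 32L) {
      readBin(bytes, "double", n = nx * ny, size = 4, endian = "little")
    } else if (fmt == 1L && bits %in% c(8L, 16L)) {
      readBin(bytes, "integer", n = nx * ny, size = bits / 8,
              signed = FALSE, endian = "little")
    } else stop("unsupported TIFF sample format", call. = FALSE)
    planes[[length(planes) + 1L]] <- t(matrix(vals, nrow = nx, ncol = ny))
    ifd <- u(ifd + 2L + n * 12L + 1L, 4L)
  }
  arr <- array(unlist(planes),
               dim = c(nrow(planes[[1]]), ncol(planes[[1]]), length(planes)))
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  voxel_stack(arr,
              voxel_xy_nm = meta$voxel_xy_nm %||% 1,
              voxel_z_nm = meta$voxel_z_nm %||% 1,
              modality = meta$modality %||% "unknown")
}
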