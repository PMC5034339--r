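# Phase-map storage: single-channel 32-bit float TIFF + JSON sidecar.
#
# Phase in radians is signed and unbounded, so the image must be stored
# as IEEE float samples.  The codec below writes a minimal uncompressed
# grayscale float32 TIFF (little-endian, single strip) and reads back
# uncompressed float32 TIFFs written by this package or by common
# scientific writers (e.g. Python tifffile), including multi-strip
# layouts and either byte order.  Anything else -- compressed, tiled, or
# integer-sample TIFFs -- is rejected with a clear error: integer TIFFs
# cannot hold phase losslessly.

TIFF_TYPE_SIZES <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `16` = 8L, `17` = 8L)

read_ifd_value <- function(con, type, count, endian) {
  here <- seek(con)
  val_raw <- readBin(con, "raw", 4)  # always consume the value field
  size <- TIFF_TYPE_SIZES[as.character(type)]
  if (is.na(size) || !type %in% c(1, 3, 4)) return(NULL)
  total <- size * count
  if (total > 4) {
    powers <- if (endian == "little") 256^(0:3) else 256^(3:0)
    offset <- sum(as.integer(val_raw) * powers)
    seek(con, offset)
  } else {
    seek(con, here)
  }
  out <- switch(as.character(type),
    `3` = readBin(con, "integer", count, size = 2, signed = FALSE, endian = endian),
    `4` = readBin(con, "integer", count, size = 4, endian = endian),
    `1` = readBin(con, "integer", count, size = 1, signed = FALSE, endian = endian),
    NULL
  )
  seek(con, here + 4)
  out
}

read_tiff_f32 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  order_mark <- readChar(con, 2, useBytes = TRUE)
  endian <- switch(order_mark, II = "little", MM = "big",
                   stopf("%s is not a TIFF file", path))
  magic <- readBin(con, "integer", 1, size = 2, endian = endian)
  if (magic != 42) stopf("%s is not a TIFF file (bad magic)", path)
  ifd_offset <- readBin(con, "integer", 1, size = 4, endian = endian)
  seek(con, ifd_offset)
  n_entries <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
  tags <- list()
  for (i in seq_len(n_entries)) {
    tag <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
    type <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
    count <- readBin(con, "integer", 1, size = 4, endian = endian)
    tags[[as.character(tag)]] <- read_ifd_value(con, type, count, endian)
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stopf("TIFF %s lacks required tag %d", path, tag)
      default
    } else v
  }
  width <- need(256)
  height <- need(257)
  bits <- need(258, 1L)
  compression <- need(259, 1L)
  sample_format <- need(339, 1L)
  samples <- need(277, 1L)
  if (compression != 1) stopf("TIFF %s is compressed; only uncompressed phase TIFFs are supported", path)
  if (samples != 1) stopf("TIFF %s has %d samples per pixel; phase maps are single-channel", path, samples)
  if (sample_format != 3 || bits[1] != 32) {
    stopf(paste0(
      "TIFF %s stores %d-bit samples of format %d; phase maps must be ",
      "32-bit IEEE float (sample format 3). Integer TIFFs cannot hold phase in radians."
    ), path, bits[1], sample_format)
  }
  offsets <- need(273)
  counts <- need(279)
  if (length(offsets) != length(counts)) stopf("TIFF %s has inconsistent strip tags", path)
  data <- numeric(0)
  for (s in seq_along(offsets)) {
    seek(con, offsets[s])
    data <- c(data, readBin(con, "numeric", counts[s] / 4, size = 4, endian = endian))
  }
  if (length(data) != width * height) {
    stopf("TIFF %s: expected %d pixels, read %d", path, width * height, length(data))
  }
  matrix(data, nrow = height, ncol = width, byrow = TRUE)
}

write_tiff_f32 <- function(values, path) {
  height <- nrow(values)
  width <- ncol(values)
  npix <- height * width
  data_bytes <- npix * 4
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL, useBytes = TRUE)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(8 + data_bytes), con, size = 4, endian = "little")  # IFD after data
  # pixel data, row-major, single strip at offset 8
  writeBin(as.numeric(t(values)), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3) {  # SHORT: value left-justified in 4-byte field
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  writeBin(10L, con, size = 2, endian = "little")  # entry count
  entry(256, 4, 1, width)
  entry(257, 4, 1, height)
  entry(258, 3, 1, 32)          # BitsPerSample
  entry(259, 3, 1, 1)           # Compression = none
  entry(262, 3, 1, 1)           # Photometric = BlackIsZero
  entry(273, 4, 1, 8)           # StripOffsets
  entry(277, 3, 1, 1)           # SamplesPerPixel
  entry(278, 4, 1, height)      # RowsPerStrip
  entry(279, 4, 1, data_bytes)  # StripByteCounts
  entry(339, 3, 1, 3)           # SampleFormat = IEEE float
  writeBin(0L, con, size = 4, endian = "little")  # no next IFD
  invisible(path)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a phase image as float32 TIFF plus JSON sidecar
#'
#' The TIFF stores the phase values as uncompressed 32-bit IEEE floats
#' (so the on-disk precision is float32); the sidecar
#' `<path-sans-ext>.json` records `{pixel_size_um, wavelength_nm}`.
#'
#' @param image A [phase_image()].
#' @param path Target TIFF path.
#' @return `path`, invisibly.
#' @export
write_phase_tiff <- function(image, path) {
  assert_phase_image(image)
  write_tiff_f32(image$values, path)
  jsonlite::write_json(
    list(pixel_size_um = image$pixel_size, wavelength_nm = image$wavelength),
    sidecar_path(path),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a phase image from float32 TIFF plus JSON sidecar
#'
#' @param path TIFF path; the sidecar `<path-sans-ext>.json` must exist
#'   and provide `pixel_size_um` and `wavelength_nm`.
#' @return A [phase_image()].  Non-finite pixels are loaded as-is;
#'   measurement functions reject them.
#' @export
read_phase_tiff <- function(path) {
  if (!file.exists(path)) stopf("phase TIFF not found: %s", path)
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    stopf("missing metadata sidecar %s (required keys: pixel_size_um, wavelength_nm)", sc)
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  for (key in c("pixel_size_um", "wavelength_nm")) {
    if (is.null(meta[[key]])) stopf("sidecar %s lacks required key '%s'", sc, key)
  }
  phase_image(read_tiff_f32(path), meta$pixel_size_um, meta$wavelength_nm)
}

#' Round a matrix to float32 storage precision
#'
#' Phase TIFFs store 32-bit floats; this helper applies the same
#' precision loss in memory, so written-then-read images can be compared
#' bit-exactly against their in-memory source.
#'
#' @param values Numeric matrix or vector.
#' @return The values after a float32 round-trip.
#' @export
as_float32 <- function(values) {
  out <- readBin(writeBin(as.numeric(values), raw(), size = 4), "numeric",
                 n = length(values), size = 4)
  if (is.matrix(values)) out <- matrix(out, nrow(values), ncol(values))
  out
}
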