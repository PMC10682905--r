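# Minimal single-band GeoTIFF I/O.
#
# Only the slice of TIFF 6.0 + GeoTIFF that this pipeline needs is
# implemented: one image, one sample per pixel, uncompressed strips,
# integer or IEEE float samples, ModelPixelScale + ModelTiepoint geometry
# and the GDAL_NODATA convention.  Anything else is an unsupported-input
# error rather than a silent misread.

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `6` = 1L,
                    `8` = 2L, `9` = 4L, `11` = 4L, `12` = 8L)

read_tiff_field <- function(con, type, count, endian) {
  switch(as.character(type),
    `1` = as.numeric(readBin(con, "integer", count, size = 1, signed = FALSE)),
    `2` = readBin(con, "raw", count),
    `3` = readBin(con, "integer", count, size = 2, signed = FALSE,
                  endian = endian),
    `4` = readBin0_long(con, count, endian),
    `6` = as.numeric(readBin(con, "integer", count, size = 1, signed = TRUE)),
    `8` = readBin(con, "integer", count, size = 2, signed = TRUE,
                  endian = endian),
    `9` = readBin(con, "integer", count, size = 4, endian = endian),
    `11` = readBin(con, "double", count, size = 4, endian = endian),
    `12` = readBin(con, "double", count, size = 8, endian = endian),
    abort_input("unsupported TIFF field type %d", type)
  )
}

# unsigned 32-bit read (R has no native uint32); values beyond 2^31 appear
# as negatives from readBin and are lifted back.
readBin0_long <- function(con, count, endian) {
  v <- readBin(con, "integer", count, size = 4, endian = endian)
  ifelse(v < 0, v + 2^32, as.numeric(v))
}

read_geotiff <- function(path, name) {
  con <- file(path, "rb")
  on.exit(close(con))
  order_bytes <- readBin(con, "raw", 2)
  endian <- if (identical(order_bytes, as.raw(c(0x49, 0x49)))) "little"
            else if (identical(order_bytes, as.raw(c(0x4d, 0x4d)))) "big"
            else abort_input("not a TIFF file: %s", path)
  magic <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
  if (magic != 42) abort_input("not a TIFF file: %s", path)
  ifd_off <- readBin0_long(con, 1, endian)
  seek(con, ifd_off)
  n_entries <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                       endian = endian)
  entries <- vector("list", n_entries)
  for (i in seq_len(n_entries)) {
    tag <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
    type <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
    count <- readBin0_long(con, 1, endian)
    value_pos <- seek(con)  # value-or-offset field starts here
    entries[[i]] <- list(tag = tag, type = type, count = count,
                         value_pos = value_pos)
    seek(con, value_pos + 4)
  }
  next_ifd <- readBin0_long(con, 1, endian)
  if (next_ifd != 0) abort_input("multi-image TIFF is unsupported: %s", path)

  get_field <- function(tag, default = NULL) {
    e <- Filter(function(x) x$tag == tag, entries)
    if (length(e) == 0) return(default)
    e <- e[[1]]
    size <- TIFF_TYPE_SIZE[as.character(e$type)] * e$count
    if (is.na(size)) abort_input("unsupported TIFF field type %d", e$type)
    seek(con, e$value_pos)
    if (size > 4) seek(con, readBin0_long(con, 1, endian))
    read_tiff_field(con, e$type, e$count, endian)
  }

  width <- get_field(256); height <- get_field(257)
  if (is.null(width) || is.null(height)) abort_input("TIFF missing dimensions")
  spp <- get_field(277, 1)
  if (spp != 1) abort_input("multi-band TIFF is unsupported: %s", path)
  if (get_field(259, 1) != 1) abort_input("compressed TIFF is unsupported")
  bits <- get_field(258, 1)
  fmt <- get_field(339, 1)  # 1 unsigned, 2 signed, 3 float
  rows_per_strip <- get_field(278, height)
  offsets <- get_field(273)
  counts <- get_field(279)
  if (is.null(offsets)) abort_input("TIFF missing strip offsets")

  read_samples <- function(n) {
    if (fmt == 3 && bits %in% c(32, 64)) {
      readBin(con, "double", n, size = bits / 8, endian = endian)
    } else if (fmt %in% c(1, 2) && bits %in% c(8, 16, 32)) {
      signed <- fmt == 2 || bits == 32
      v <- readBin(con, "integer", n, size = bits / 8, signed = signed,
                   endian = endian)
      as.numeric(v)
    } else {
      abort_input("unsupported TIFF sample format (%d bits, format %d)",
                  bits, fmt)
    }
  }
  vals <- numeric(0)
  for (s in seq_along(offsets)) {
    seek(con, offsets[s])
    n_rows_here <- min(rows_per_strip, height - (s - 1) * rows_per_strip)
    vals <- c(vals, read_samples(n_rows_here * width))
  }
  if (length(vals) != width * height) abort_input("TIFF pixel data truncated")
  m <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)

  scale <- get_field(33550)
  tie <- get_field(33922)
  if (is.null(scale) || is.null(tie)) {
    abort_input("TIFF lacks GeoTIFF georeferencing tags")
  }
  if (abs(scale[1] - scale[2]) > 1e-9) {
    abort_input("non-square GeoTIFF cells are unsupported")
  }
  x_origin <- tie[4] - tie[1] * scale[1]
  y_origin <- tie[5] + tie[2] * scale[2]
  geom <- grid_geometry(height, width, x_origin, y_origin, scale[1])

  nodata_raw <- get_field(42113)
  mask <- !is.finite(m)
  if (!is.null(nodata_raw)) {
    nodata <- suppressWarnings(as.numeric(rawToChar(nodata_raw[nodata_raw != 0])))
    if (is.finite(nodata)) {
      # values went through float32; compare at float32 precision
      mask <- mask | abs(m - nodata) <= abs(nodata) * 1e-6
    }
  }
  env_layer(name, geom, m, mask)
}

write_geotiff <- function(layer, path, nodata = -9999) {
  g <- layer$geometry
  v <- t(layer$values)  # row-major emission
  v[t(layer$nodata_mask)] <- nodata
  nodata_str <- c(charToRaw(formatC(nodata, digits = 17, format = "g")),
                  as.raw(0))
  n_pix <- g$n_rows * g$n_cols

  geokeys <- as.integer(c(1, 1, 0, 3,
                          1024, 0, 1, 2,    # model type: geographic
                          1025, 0, 1, 1,    # raster type: pixel-is-area
                          2048, 0, 1, 4326))
  scale <- c(g$cell_size, g$cell_size, 0)
  tie <- c(0, 0, 0, g$x_origin, g$y_origin, 0)

  header_len <- 8L
  n_tags <- 15L
  ifd_len <- 2L + n_tags * 12L + 4L
  off_scale <- header_len + ifd_len
  off_tie <- off_scale + 24L
  off_keys <- off_tie + 48L
  off_nodata <- off_keys + 2L * length(geokeys)
  off_data <- off_nodata + length(nodata_str)
  if (off_data %% 2L == 1L) off_data <- off_data + 1L

  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(as.raw(c(0x49, 0x49)), con); w16(42); w32(header_len)
  w16(n_tags)
  entry <- function(tag, type, count, value, inline_short = type == 3) {
    w16(tag); w16(type); w32(count)
    if (inline_short && count == 1) { w16(value); w16(0) } else w32(value)
  }
  entry(256, 4, 1, g$n_cols, inline_short = FALSE)
  entry(257, 4, 1, g$n_rows, inline_short = FALSE)
  entry(258, 3, 1, 32)
  entry(259, 3, 1, 1)
  entry(262, 3, 1, 1)
  entry(273, 4, 1, off_data, inline_short = FALSE)
  entry(277, 3, 1, 1)
  entry(278, 4, 1, g$n_rows, inline_short = FALSE)
  entry(279, 4, 1, n_pix * 4L, inline_short = FALSE)
  entry(284, 3, 1, 1)
  entry(339, 3, 1, 3)
  entry(33550, 12, 3, off_scale, inline_short = FALSE)
  entry(33922, 12, 6, off_tie, inline_short = FALSE)
  entry(34735, 3, length(geokeys), off_keys, inline_short = FALSE)
  entry(42113, 2, length(nodata_str), off_nodata, inline_short = FALSE)
  w32(0)  # no next IFD
  writeBin(scale, con, size = 8, endian = "little")
  writeBin(tie, con, size = 8, endian = "little")
  w16(geokeys)
  writeBin(nodata_str, con)
  while (seek(con) < off_data) writeBin(as.raw(0), con)
  writeBin(as.vector(v), con, size = 4, endian = "little")
  invisible(path)
}
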