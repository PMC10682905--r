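#' Read a single-band raster file
#'
#' Supports the two dialects the pipeline exchanges: ESRI ASCII grid
#' (`ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` header) and
#' single-band uncompressed GeoTIFF.  The dialect is sniffed from the file's
#' leading bytes.  The nodata value is folded into the layer's mask.
#'
#' @param path file path.
#' @param name layer name; defaults to the file stem.
#' @return an [env_layer()].
#' @export
read_raster <- function(path, name = NULL) {
  if (!file.exists(path)) abort_input("cannot read raster: %s", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  magic <- readBin(path, "raw", n = 4L)
  if (length(magic) >= 4 &&
      (identical(magic[1:2], as.raw(c(0x49, 0x49))) ||
       identical(magic[1:2], as.raw(c(0x4d, 0x4d))))) {
    return(read_geotiff(path, name))
  }
  read_ascii_grid(path, name)
}

#' Write a single-band raster file
#'
#' Round-trip contract: `read_raster(write_raster(layer, p))` reproduces the
#' layer's geometry and its values on unmasked cells.  The ASCII dialect
#' writes values with 17 significant digits so doubles survive; the GeoTIFF
#' dialect stores float32 (values are rounded to float32 precision).
#'
#' @param layer an [env_layer()].
#' @param path output path.
#' @param dialect `"ascii"` or `"geotiff"`.
#' @param nodata value written into masked cells.
#' @return `path`, invisibly.
#' @export
write_raster <- function(layer, path, dialect = c("ascii", "geotiff"),
                         nodata = -9999) {
  dialect <- match.arg(dialect)
  if (dialect == "ascii") write_ascii_grid(layer, path, nodata)
  else write_geotiff(layer, path, nodata)
  invisible(path)
}

read_ascii_grid <- function(path, name) {
  head_lines <- readLines(path, n = 6L, warn = FALSE)
  kv <- list()
  n_header <- 0L
  for (ln in head_lines) {
    parts <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z_]+$", parts[1]) &&
        !is.na(suppressWarnings(as.numeric(parts[2])))) {
      kv[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_header <- n_header + 1L
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(kv)) ||
      !any(c("xllcorner", "xllcenter") %in% names(kv))) {
    abort_input("not a parseable ESRI ASCII grid: %s", path)
  }
  nc <- as.integer(kv$ncols); nr <- as.integer(kv$nrows)
  cs <- kv$cellsize
  xll <- if (!is.null(kv$xllcorner)) kv$xllcorner else kv$xllcenter - cs / 2
  yll <- if (!is.null(kv$yllcorner)) kv$yllcorner else kv$yllcenter - cs / 2
  nodata <- kv$nodata_value %||% -9999
  vals <- scan(path, what = numeric(), skip = n_header, quiet = TRUE)
  if (length(vals) != nr * nc) {
    abort_input("ASCII grid %s has %d values, expected %d", path,
                length(vals), nr * nc)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  mask <- m == nodata | !is.finite(m)
  geom <- grid_geometry(nr, nc, xll, yll + nr * cs, cs)
  env_layer(name, geom, m, mask)
}

write_ascii_grid <- function(layer, path, nodata = -9999) {
  g <- layer$geometry
  v <- layer$values
  v[layer$nodata_mask] <- nodata
  num <- function(x) formatC(x, digits = 17, format = "g")
  header <- c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %s", num(g$x_origin)),
    sprintf("yllcorner %s", num(g$y_origin - g$n_rows * g$cell_size)),
    sprintf("cellsize %s", num(g$cell_size)),
    sprintf("NODATA_value %s", num(nodata))
  )
  body <- apply(v, 1, function(r) paste(num(r), collapse = " "))
  con <- file(path, "wb")  # binary mode: fixed \n line endings
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read and write environment stacks as raster directories
#'
#' A stack is exchanged as one raster file per layer inside a directory.
#'
#' @param dir directory holding `<name>.asc` / `<name>.tif` files.
#' @param names optional layer names (file stems) to read, in order.
#' @return an [env_stack()].
#' @export
read_stack <- function(dir, names = NULL) {
  files <- list.files(dir, pattern = "\\.(asc|tif|tiff)$", full.names = TRUE)
  if (!is.null(names)) {
    stems <- sub("\\.[^.]*$", "", basename(files))
    files <- files[match(names, stems)]
    if (anyNA(files)) abort_input("missing layers in %s", dir)
  }
  if (length(files) == 0) abort_input("no raster files in %s", dir)
  env_stack(lapply(files, read_raster))
}

#' @rdname read_stack
#' @param stack an [env_stack()].
#' @param dialect raster dialect, see [write_raster()].
#' @export
write_stack <- function(stack, dir, dialect = "ascii") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (dialect == "ascii") "asc" else "tif"
  for (l in stack$layers) {
    write_raster(l, file.path(dir, paste0(l$name, ".", ext)), dialect)
  }
  invisible(dir)
}
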