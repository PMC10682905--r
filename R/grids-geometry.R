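#' Grid geometry for regular lon/lat rasters
#'
#' Describes a regular grid of square cells in geographic coordinates.
#' `x_origin`/`y_origin` are the coordinates of the *outer* corner of the
#' top-left cell (west edge, north edge); rows run north to south, columns
#' west to east, values are stored row-major from the top row.  A cell's
#' location, for every point-in-cell and cell-in-polygon test in the package,
#' is its center.
#'
#' @param n_rows,n_cols positive integers.
#' @param x_origin,y_origin degrees; outer corner of the top-left cell.
#' @param cell_size degrees per (square) cell; must be positive.
#' @param crs_tag free-text CRS label, default geographic lon/lat.
#' @return an object of class `grid_geometry`.
#' @export
grid_geometry <- function(n_rows, n_cols, x_origin, y_origin, cell_size,
                          crs_tag = "EPSG:4326 lon/lat") {
  if (n_rows < 1 || n_cols < 1) abort_input("grid must have positive dimensions")
  if (!is.finite(cell_size) || cell_size <= 0) abort_input("cell_size must be > 0")
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         x_origin = as.numeric(x_origin), y_origin = as.numeric(y_origin),
         cell_size = as.numeric(cell_size), crs_tag = crs_tag),
    class = "grid_geometry"
  )
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry %d x %d @ %g deg, origin (%g, %g)>\n",
              x$n_rows, x$n_cols, x$cell_size, x$x_origin, x$y_origin))
  invisible(x)
}

# Two geometries are co-registered iff all five numeric fields agree to 1e-9.
#' Test whether two grid geometries are co-registered
#' @param a,b `grid_geometry` objects.
#' @param tol numeric tolerance in degrees/cells.
#' @return logical.
#' @export
geom_equal <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$x_origin - b$x_origin) < tol &&
    abs(a$y_origin - b$y_origin) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

stopifnot_coregistered <- function(a, b) {
  if (!geom_equal(a, b)) abort_input("grids are not co-registered")
  invisible(TRUE)
}

#' Cell-center coordinates of a grid
#'
#' @param geometry a `grid_geometry`.
#' @return list with `x` (length `n_cols`) and `y` (length `n_rows`, north to
#'   south) center coordinates, plus matrices `xm`, `ym` in storage order.
#' @export
cell_centers <- function(geometry) {
  x <- geometry$x_origin + (seq_len(geometry$n_cols) - 0.5) * geometry$cell_size
  y <- geometry$y_origin - (seq_len(geometry$n_rows) - 0.5) * geometry$cell_size
  list(x = x, y = y,
       xm = matrix(x, geometry$n_rows, geometry$n_cols, byrow = TRUE),
       ym = matrix(y, geometry$n_rows, geometry$n_cols))
}

# Half-open cell assignment: a point belongs to the cell with
# x in [left, right) and y in (bottom, top].  This makes extraction
# bit-reproducible on cell boundaries.
#' Locate points on a grid
#' @param geometry a `grid_geometry`.
#' @param lon,lat coordinate vectors.
#' @return list of integer vectors `row`, `col`; `NA` for points off the grid.
#' @export
locate_cells <- function(geometry, lon, lat) {
  col <- floor((lon - geometry$x_origin) / geometry$cell_size) + 1
  row <- ceiling((geometry$y_origin - lat) / geometry$cell_size)
  row[lat == geometry$y_origin] <- 1L  # top edge belongs to row 1
  bad <- col < 1 | col > geometry$n_cols | row < 1 | row > geometry$n_rows |
    !is.finite(lon) | !is.finite(lat)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Construct a raster layer
#'
#' @param name layer name, e.g. `"bio2"`.
#' @param geometry a `grid_geometry`.
#' @param values numeric matrix `n_rows x n_cols` (row 1 = northernmost).
#' @param nodata_mask logical matrix, `TRUE` where the cell carries no data.
#'   Defaults to the non-finite cells of `values`.
#' @return object of class `env_layer`.
#' @export
env_layer <- function(name, geometry, values, nodata_mask = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != geometry$n_rows || ncol(values) != geometry$n_cols) {
    abort_input("values shape does not match geometry")
  }
  if (is.null(nodata_mask)) nodata_mask <- !is.finite(values)
  nodata_mask <- nodata_mask | !is.finite(values)
  values[nodata_mask] <- NA_real_
  structure(list(name = name, geometry = geometry, values = values,
                 nodata_mask = nodata_mask),
            class = "env_layer")
}

#' @export
print.env_layer <- function(x, ...) {
  cat(sprintf("<env_layer '%s' %d x %d, %d nodata>\n", x$name,
              x$geometry$n_rows, x$geometry$n_cols, sum(x$nodata_mask)))
  invisible(x)
}

#' Bundle co-registered layers into an environment stack
#'
#' @param layers list of `env_layer` objects sharing one geometry and with
#'   unique names.
#' @return object of class `env_stack` with a `valid_mask` equal to the
#'   conjunction of the per-layer data masks.
#' @export
env_stack <- function(layers) {
  if (length(layers) < 1) abort_input("env_stack needs at least one layer")
  nms <- vapply(layers, function(l) l$name, character(1))
  if (anyDuplicated(nms)) abort_input("layer names must be unique")
  geom <- layers[[1]]$geometry
  for (l in layers) stopifnot_coregistered(geom, l$geometry)
  valid <- Reduce(`&`, lapply(layers, function(l) !l$nodata_mask))
  names(layers) <- nms
  structure(list(layers = layers, geometry = geom, valid_mask = valid),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack %d layers (%s) %d x %d, %d valid cells>\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              x$geometry$n_rows, x$geometry$n_cols, sum(x$valid_mask)))
  invisible(x)
}

#' Layer names of a stack
#' @param stack an `env_stack`.
#' @return character vector.
#' @export
stack_names <- function(stack) names(stack$layers)

#' Environment matrix of the valid cells of a stack
#'
#' @param stack an `env_stack`.
#' @param cells optional integer vector of cell indices (column-major into the
#'   value matrices); default = all valid cells.
#' @return numeric matrix `cells x variables` with a `cells` attribute holding
#'   the cell indices.
#' @export
stack_values <- function(stack, cells = NULL) {
  if (is.null(cells)) cells <- which(stack$valid_mask)
  out <- vapply(stack$layers, function(l) l$values[cells],
                numeric(length(cells)))
  out <- matrix(out, nrow = length(cells),
                dimnames = list(NULL, names(stack$layers)))
  attr(out, "cells") <- cells
  out
}

#' Unmasked-pixel area of a mask or layer
#'
#' The paper-facing "area" unit of the package is the unmasked pixel count;
#' a cosine-of-latitude weighted variant is available because geographic
#' cells shrink with latitude.
#'
#' @param mask logical matrix (`TRUE` = counted) or an `env_layer` (counts
#'   its data cells).
#' @param geometry `grid_geometry`, required for `weighted = TRUE`.
#' @param weighted if `TRUE`, sum `cos(latitude)` over counted cells instead
#'   of counting.
#' @return numeric scalar.
#' @export
pixel_area <- function(mask, geometry = NULL, weighted = FALSE) {
  if (inherits(mask, "env_layer")) {
    geometry <- mask$geometry
    mask <- !mask$nodata_mask
  }
  if (!weighted) return(sum(mask))
  if (is.null(geometry)) abort_input("weighted area needs a geometry")
  cc <- cell_centers(geometry)
  w <- matrix(cos(cc$y * pi / 180), geometry$n_rows, geometry$n_cols)
  sum(w[mask])
}
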