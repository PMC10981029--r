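#' Define a raster grid
#'
#' A `grid_spec` describes the spatial frame shared by all layers of an
#' analysis: pixel counts, the affine geometry (lower-left corner and square
#' cell size), a CRS identifier and the nodata sentinel used on disk. Row 1 is
#' the top (northernmost) row and columns run west to east, the usual raster
#' convention. Extents are half-open: a point on the lower/western edge of a
#' cell belongs to that cell.
#'
#' @param n_rows,n_cols Pixel counts (positive integers).
#' @param xmin,ymin Coordinates of the lower-left corner of the grid, in CRS
#'   units (metres for projected systems).
#' @param cellsize Square pixel size in CRS units; must be positive.
#' @param crs CRS identifier string (e.g. `"EPSG:32632"`), or `NA` when
#'   unknown.
#' @param nodata Numeric sentinel written to files for invalid cells.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(50, 50, cellsize = 300)
#' g
#' @export
grid_spec <- function(n_rows, n_cols, xmin = 0, ymin = 0, cellsize = 300,
                      crs = "EPSG:32632", nodata = -9999) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (length(n_rows) != 1L || length(n_cols) != 1L ||
      is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L) {
    stop("n_rows and n_cols must be single integers >= 1")
  }
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0) {
    stop("cellsize must be a single positive number")
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         xmin = as.numeric(xmin), ymin = as.numeric(ymin),
         cellsize = as.numeric(cellsize),
         crs = if (is.null(crs)) NA_character_ else as.character(crs),
         nodata = as.numeric(nodata)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells, cellsize %g, origin (%g, %g), crs %s\n",
              x$n_rows, x$n_cols, x$cellsize, x$xmin, x$ymin,
              ifelse(is.na(x$crs), "<unset>", x$crs)))
  invisible(x)
}

# xmax/ymax of the (half-open) extent
grid_xmax <- function(g) g$xmin + g$n_cols * g$cellsize
grid_ymax <- function(g) g$ymin + g$n_rows * g$cellsize

#' Cell-center coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @return A list with `x` (length `n_cols`, west to east) and `y`
#'   (length `n_rows`, north to south, matching row order).
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  list(x = grid$xmin + (seq_len(grid$n_cols) - 0.5) * grid$cellsize,
       y = grid_ymax(grid) - (seq_len(grid$n_rows) - 0.5) * grid$cellsize)
}

#' Test whether two grids describe the same spatial frame
#'
#' @param a,b [grid_spec()] objects.
#' @param tol Numeric tolerance on the geometry.
#' @return `TRUE` or `FALSE`.
#' @export
grids_equal <- function(a, b, tol = 1e-9) {
  inherits(a, "grid_spec") && inherits(b, "grid_spec") &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol &&
    abs(a$cellsize - b$cellsize) < tol &&
    (is.na(a$crs) || is.na(b$crs) || identical(a$crs, b$crs))
}

stop_if_grid_mismatch <- function(a, b, what = "layers") {
  if (!grids_equal(a, b)) stop(sprintf("%s are on different grids", what))
  invisible(TRUE)
}
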