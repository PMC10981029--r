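#' Bundle a time-ordered stack of composites
#'
#' A `composite_stack` holds a dense time series of rasters on a common grid:
#' a `[time, row, col]` value array, a validity mask of the same shape, and
#' the strictly increasing composite dates. NDVI stacks hold the per-period
#' productivity values that the habitat-index components summarise.
#'
#' @param values Numeric array `[time, row, col]`.
#' @param dates `Date` vector, one per time slice, strictly increasing.
#' @param grid A [grid_spec()] matching the spatial dimensions.
#' @param valid Optional logical array of the same shape; defaults to
#'   `!is.na(values)`.
#' @param range Admissible value range for valid cells; `c(-1, 1)` for
#'   NDVI. Use `NULL` for an unbounded productivity measure.
#' @return An object of class `composite_stack`.
#' @export
composite_stack <- function(values, dates, grid, valid = NULL,
                            range = c(-1, 1)) {
  stopifnot(is.array(values), length(dim(values)) == 3L,
            inherits(grid, "grid_spec"))
  dates <- as.Date(dates)
  d <- dim(values)
  if (d[1] != length(dates)) stop("one date per time slice required")
  if (d[2] != grid$n_rows || d[3] != grid$n_cols) {
    stop("value array does not match the grid dimensions")
  }
  if (length(dates) > 1L && any(diff(as.numeric(dates)) <= 0)) {
    stop("composite dates must be strictly increasing")
  }
  if (is.null(valid)) valid <- !is.na(values)
  stopifnot(is.logical(valid), identical(dim(valid), d))
  values[!valid] <- NA_real_
  if (!is.null(range)) {
    bad <- valid & (values < range[1] | values > range[2])
    if (any(bad, na.rm = TRUE)) {
      stop(sprintf("valid values outside [%g, %g]", range[1], range[2]))
    }
  }
  structure(list(values = values, valid = valid, dates = dates, grid = grid),
            class = "composite_stack")
}

#' @export
print.composite_stack <- function(x, ...) {
  cat(sprintf("composite_stack: %d composites (%s .. %s), %d x %d pixels\n",
              length(x$dates), format(min(x$dates)), format(max(x$dates)),
              x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

# ---- ASCII-grid I/O ---------------------------------------------------------
# Rasters are stored as ESRI ASCII grids (.asc): a 6-line header (NCOLS,
# NROWS, XLLCORNER, YLLCORNER, CELLSIZE, NODATA_VALUE) followed by rows from
# north to south. The format is plain text, georeferenced, and read by every
# mainstream GIS. The CRS, which the .asc header cannot carry, goes in an
# optional JSON sidecar (<file>.json).

#' Write a single-band raster to an ASCII grid file
#'
#' Values are written with full double precision so a write/read round trip
#' is bit-exact. `NA` cells are written as the grid's nodata sentinel. A JSON
#' sidecar `<path>.json` records the CRS (and any extra metadata supplied).
#'
#' @param values Numeric matrix `[n_rows, n_cols]`, row 1 = north.
#' @param grid A [grid_spec()].
#' @param path Output file path (conventionally `.asc`).
#' @param sidecar Write the JSON sidecar? Default `TRUE`.
#' @param extra Named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_raster <- function(values, grid, path, sidecar = TRUE, extra = list()) {
  stopifnot(is.matrix(values), inherits(grid, "grid_spec"))
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols) {
    stop("matrix dimensions do not match the grid")
  }
  v <- values
  v[is.na(v)] <- grid$nodata
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("NCOLS %d", grid$n_cols),
    sprintf("NROWS %d", grid$n_rows),
    sprintf("XLLCORNER %.10g", grid$xmin),
    sprintf("YLLCORNER %.10g", grid$ymin),
    sprintf("CELLSIZE %.10g", grid$cellsize),
    sprintf("NODATA_VALUE %.10g", grid$nodata)
  ), con)
  writeLines(apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")),
             con)
  if (sidecar) {
    meta <- c(list(crs = grid$crs), extra)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a single-band ASCII grid raster
#'
#' @param path File path; a `<path>.json` sidecar, if present, supplies the
#'   CRS.
#' @return A list with `values` (matrix, `NA` at nodata cells) and `grid`
#'   (a [grid_spec()]).
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop(sprintf("raster file not found: %s", path))
  hdr_lines <- readLines(path, n = 6L)
  hdr <- strsplit(trimws(hdr_lines), "\\s+")
  keys <- toupper(vapply(hdr, `[`, "", 1L))
  vals <- vapply(hdr, `[`, "", 2L)
  need <- c("NCOLS", "NROWS", "XLLCORNER", "YLLCORNER", "CELLSIZE",
            "NODATA_VALUE")
  if (!all(need %in% keys)) {
    stop(sprintf("not a georeferenced ASCII grid (bad header): %s", path))
  }
  h <- as.numeric(vals[match(need, keys)])
  names(h) <- need
  crs <- NA_character_
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc)
    if (!is.null(meta$crs)) crs <- as.character(meta$crs)
  }
  grid <- grid_spec(h["NROWS"], h["NCOLS"], h["XLLCORNER"], h["YLLCORNER"],
                    h["CELLSIZE"], crs = crs, nodata = h["NODATA_VALUE"])
  vals <- scan(path, what = double(), skip = 6L, quiet = TRUE)
  if (length(vals) != grid$n_rows * grid$n_cols) {
    stop(sprintf("wrong cell count in %s: expected %d, found %d",
                 path, grid$n_rows * grid$n_cols, length(vals)))
  }
  m <- matrix(vals, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
  m[m == grid$nodata] <- NA_real_
  list(values = m, grid = grid)
}

#' Write a composite stack as one ASCII grid per composite plus a manifest
#'
#' @param stack A [composite_stack()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; files are `<prefix>_<date>.asc`.
#' @return Path of the JSON manifest, invisibly.
#' @export
write_stack <- function(stack, dir, prefix = "composite") {
  stopifnot(inherits(stack, "composite_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(stack$dates))
  for (i in seq_along(stack$dates)) {
    f <- file.path(dir, sprintf("%s_%s.asc", prefix, format(stack$dates[i])))
    write_raster(stack$values[i, , ], stack$grid, f, sidecar = FALSE)
    files[i] <- basename(f)
  }
  manifest <- file.path(dir, sprintf("%s_stack.json", prefix))
  jsonlite::write_json(
    list(crs = stack$grid$crs, dates = format(stack$dates), files = files),
    manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a composite stack written by [write_stack()]
#'
#' @param manifest Path to the `<prefix>_stack.json` manifest.
#' @return A [composite_stack()].
#' @export
read_stack <- function(manifest) {
  if (!file.exists(manifest)) stop(sprintf("stack manifest not found: %s", manifest))
  meta <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  dir <- dirname(manifest)
  first <- read_raster(file.path(dir, meta$files[1]))
  g <- first$grid
  g$crs <- if (is.null(meta$crs) || is.na(meta$crs)) g$crs else meta$crs
  vals <- array(NA_real_, c(length(meta$files), g$n_rows, g$n_cols))
  vals[1, , ] <- first$values
  for (i in seq_along(meta$files)[-1]) {
    r <- read_raster(file.path(dir, meta$files[i]))
    stop_if_grid_mismatch(g, r$grid, "stack bands")
    vals[i, , ] <- r$values
  }
  composite_stack(vals, as.Date(meta$dates), g)
}

# ---- grid alignment ---------------------------------------------------------

#' Resample a raster onto a target grid
#'
#' Brings layers from their native resolution onto the common analysis grid.
#' Continuous fields use `bilinear` when refining and `mean_aggregate` when
#' coarsening; categorical fields use `nearest`; binary fine-scale masks use
#' `fraction`, the proportion of valid fine cells that are positive within
#' each coarse cell (turn into a mask with [binarize_fraction()]).
#'
#' @param values Source matrix (`NA` = invalid).
#' @param src_grid,target [grid_spec()] objects; CRSs must agree when both
#'   are set.
#' @param method One of `"bilinear"`, `"nearest"`, `"mean_aggregate"`,
#'   `"fraction"`.
#' @return Matrix on the target grid; cells outside the overlap, or coarse
#'   cells receiving no source cell, are `NA`.
#' @export
align_to_grid <- function(values, src_grid, target,
                          method = c("bilinear", "nearest", "mean_aggregate",
                                     "fraction")) {
  method <- match.arg(method)
  stopifnot(is.matrix(values), inherits(src_grid, "grid_spec"),
            inherits(target, "grid_spec"))
  if (!is.na(src_grid$crs) && !is.na(target$crs) &&
      !identical(src_grid$crs, target$crs)) {
    stop(sprintf("CRS mismatch: source %s vs target %s",
                 src_grid$crs, target$crs))
  }
  if (grid_xmax(src_grid) <= target$xmin || src_grid$xmin >= grid_xmax(target) ||
      grid_ymax(src_grid) <= target$ymin || src_grid$ymin >= grid_ymax(target)) {
    stop("source and target extents do not overlap")
  }
  if (grids_equal(src_grid, target)) return(values)

  out <- matrix(NA_real_, target$n_rows, target$n_cols)
  if (method %in% c("mean_aggregate", "fraction")) {
    # bin source cell centers into target cells
    cc <- cell_centers(src_grid)
    tc <- floor((cc$x - target$xmin) / target$cellsize) + 1L
    tr <- floor((grid_ymax(target) - cc$y) / target$cellsize) + 1L
    okc <- tc >= 1L & tc <= target$n_cols
    okr <- tr >= 1L & tr <= target$n_rows
    idx_r <- matrix(tr, src_grid$n_rows, src_grid$n_cols)
    idx_c <- matrix(tc, src_grid$n_rows, src_grid$n_cols, byrow = TRUE)
    keep <- outer(okr, okc, "&") & !is.na(values)
    if (any(keep)) {
      cell <- (idx_r[keep] - 1L) * target$n_cols + idx_c[keep]
      v <- values[keep]
      if (method == "fraction") v <- as.numeric(v > 0)
      sums <- rowsum(v, cell)
      cnts <- rowsum(rep(1, length(v)), cell)
      ids <- as.integer(rownames(sums))
      out[cbind((ids - 1L) %/% target$n_cols + 1L,
                (ids - 1L) %% target$n_cols + 1L)] <- sums / cnts
    }
  } else {
    cc <- cell_centers(target)
    # fractional position in source index space (1 = first center)
    fx <- (cc$x - src_grid$xmin) / src_grid$cellsize + 0.5
    fy <- (grid_ymax(src_grid) - cc$y) / src_grid$cellsize + 0.5
    inx <- cc$x >= src_grid$xmin & cc$x < grid_xmax(src_grid)
    iny <- cc$y > src_grid$ymin & cc$y <= grid_ymax(src_grid)
    if (method == "nearest") {
      jc <- pmin(pmax(round(fx), 1L), src_grid$n_cols)
      jr <- pmin(pmax(round(fy), 1L), src_grid$n_rows)
      for (r in which(iny)) out[r, inx] <- values[jr[r], jc[inx]]
    } else { # bilinear, clamped at the source margins
      c0 <- pmin(pmax(floor(fx), 1L), src_grid$n_cols - 1L)
      r0 <- pmin(pmax(floor(fy), 1L), src_grid$n_rows - 1L)
      if (src_grid$n_cols == 1L) c0 <- rep(1L, length(fx))
      if (src_grid$n_rows == 1L) r0 <- rep(1L, length(fy))
      wx <- pmin(pmax(fx - c0, 0), 1)
      wy <- pmin(pmax(fy - r0, 0), 1)
      c1 <- pmin(c0 + 1L, src_grid$n_cols)
      r1 <- pmin(r0 + 1L, src_grid$n_rows)
      for (r in which(iny)) {
        v00 <- values[r0[r], c0]; v01 <- values[r0[r], c1]
        v10 <- values[r1[r], c0]; v11 <- values[r1[r], c1]
        res <- (1 - wy[r]) * ((1 - wx) * v00 + wx * v01) +
          wy[r] * ((1 - wx) * v10 + wx * v11)
        out[r, inx] <- res[inx]
      }
    }
  }
  out
}

#' Threshold a fraction raster into a binary mask
#'
#' @param values Matrix of fractions in `[0, 1]` (e.g. from
#'   [align_to_grid()] with `method = "fraction"`).
#' @param threshold Cells with fraction `>= threshold` become positive.
#' @return Logical matrix (`NA` preserved).
#' @export
binarize_fraction <- function(values, threshold = 0.5) {
  stopifnot(is.matrix(values))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1) {
    stop("threshold must be a single number in [0, 1]")
  }
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stop("fraction values must lie in [0, 1]")
  values >= threshold
}
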