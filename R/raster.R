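#' In-memory georeferenced raster
#'
#' A light-weight planar raster: a list of equally sized numeric band
#' matrices plus the grid geometry.  Coordinates are planar meters and the
#' package never reprojects them; any CRS string supplied is carried along
#' opaquely.  The grid convention, shared by every function in the
#' package, is: row 1 / column 1 is the top-left pixel, pixel extents are
#' half-open, and the centre of pixel `(r, c)` lies at
#' `origin + ((c - 0.5) * cell, -(r - 0.5) * cell)`.
#'
#' @param bands a numeric matrix or list of numeric matrices with equal
#'   dimensions (rows = y, columns = x).
#' @param cell_size_m pixel size in meters (> 0).
#' @param origin numeric length 2, map coordinates `(x, y)` of the
#'   top-left corner of the grid.
#' @param role one of `"imagery"`, `"dsm"`, `"dtm"`, `"chm"`, `"texture"`,
#'   `"classmap"`, `"segmentmap"`.
#' @param band_names optional character names for the bands.
#' @param crs optional CRS description, carried but never interpreted.
#' @return an object of class `canopy_raster`.
#' @export
canopy_raster <- function(bands, cell_size_m, origin = c(0, 0),
                          role = "imagery", band_names = NULL, crs = NULL) {
  if (is.matrix(bands)) bands <- list(bands)
  if (!is.list(bands) || !length(bands) ||
      !all(vapply(bands, is.matrix, logical(1))))
    abort("`bands` must be a matrix or a non-empty list of matrices")
  dims <- vapply(bands, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    abort("all bands must share the same dimensions")
  check_scalar(cell_size_m, "cell_size_m", positive = TRUE)
  if (length(origin) != 2L || !all(is.finite(origin)))
    abort("`origin` must be two finite map coordinates (x, y)")
  role <- match.arg(role, c("imagery", "dsm", "dtm", "chm", "texture",
                            "classmap", "segmentmap"))
  if (is.null(band_names))
    band_names <- paste0("band", seq_along(bands))
  if (length(band_names) != length(bands) || anyDuplicated(band_names))
    abort("`band_names` must be unique and match the number of bands")
  names(bands) <- band_names
  structure(list(bands = bands, cell_size_m = cell_size_m,
                 origin = as.numeric(origin), role = role, crs = crs),
            class = "canopy_raster")
}

#' @export
print.canopy_raster <- function(x, ...) {
  d <- dim(x$bands[[1]])
  cat(sprintf(
    "<canopy_raster> role=%s  %d x %d px, %d band(s), cell %.3g m\n",
    x$role, d[1], d[2], length(x$bands), x$cell_size_m))
  cat(sprintf("  origin (%.3f, %.3f)  bands: %s\n", x$origin[1],
              x$origin[2], paste(names(x$bands), collapse = ", ")))
  invisible(x)
}

#' @export
dim.canopy_raster <- function(x) dim(x$bands[[1]])

#' Number of bands of a raster
#' @param r a [canopy_raster].
#' @return integer band count.
#' @export
n_bands <- function(r) length(r$bands)

#' Extract one band as a matrix
#' @param r a [canopy_raster].
#' @param i band index or name.
#' @return numeric matrix.
#' @export
rast_band <- function(r, i = 1L) r$bands[[i]]

#' Map coordinates of pixel centres
#'
#' @param r a [canopy_raster].
#' @return list with `x` (length = columns) and `y` (length = rows) of
#'   pixel-centre coordinates following the package grid convention.
#' @export
pixel_centers <- function(r) {
  d <- dim(r)
  list(x = r$origin[1] + (seq_len(d[2]) - 0.5) * r$cell_size_m,
       y = r$origin[2] - (seq_len(d[1]) - 0.5) * r$cell_size_m)
}

#' Locate map coordinates on the raster grid
#'
#' @param r a [canopy_raster].
#' @param x,y map coordinates (meters).
#' @return data.frame with columns `row`, `col`; `NA` for points outside
#'   the grid.
#' @export
cell_at <- function(r, x, y) {
  d <- dim(r)
  col <- floor((x - r$origin[1]) / r$cell_size_m) + 1
  row <- floor((r$origin[2] - y) / r$cell_size_m) + 1
  bad <- !is.finite(row) | !is.finite(col) |
    row < 1 | row > d[1] | col < 1 | col > d[2]
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

# TRUE when two rasters share shape, origin and cell size
same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a), dim(b)) &&
    abs(a$cell_size_m - b$cell_size_m) < tol &&
    all(abs(a$origin - b$origin) < tol)
}

geometry_string <- function(r) {
  d <- dim(r)
  sprintf("%dx%d px, cell %.6g m, origin (%.6g, %.6g)", d[1], d[2],
          r$cell_size_m, r$origin[1], r$origin[2])
}
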