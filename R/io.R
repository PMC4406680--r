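#' Read and write rasters
#'
#' Two on-disk forms are supported. `*.tif`/`*.tiff`: pixel values are
#' stored as 32-bit float TIFF via the `tiff` package; because libtiff
#' float storage is defined on `[0, 1]`, each band is min-max normalised
#' on write and the normalisation, grid geometry, band names, role and
#' nodata value travel in a JSON sidecar (`<file>.aux.json`).  Roundtrips
#' are lossless to float32 relative precision (~1e-7).  `*.asc`: a
#' single-band ESRI ASCII grid, plain text and exactly
#' printed-precision-lossless; multi-band rasters are refused for `.asc`.
#'
#' @param r a [canopy_raster].
#' @param path file path ending in `.tif`, `.tiff` or `.asc`.
#' @return `read_raster` returns a [canopy_raster]; `write_raster`
#'   returns `path` invisibly.
#' @export
write_raster <- function(r, path) {
  stopifnot(inherits(r, "canopy_raster"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    lo <- vapply(r$bands, function(b) suppressWarnings(min(b, na.rm = TRUE)),
                 numeric(1))
    hi <- vapply(r$bands, function(b) suppressWarnings(max(b, na.rm = TRUE)),
                 numeric(1))
    lo[!is.finite(lo)] <- 0; hi[!is.finite(hi)] <- 0
    span <- ifelse(hi > lo, hi - lo, 1)
    d <- dim(r)
    arr <- array(0, c(d[1], d[2], length(r$bands)))
    for (b in seq_along(r$bands)) {
      v <- (r$bands[[b]] - lo[b]) / span[b]
      v[is.na(v)] <- -1       # nodata sentinel, outside [0,1] is clipped,
      arr[, , b] <- pmax(v, 0) # so mark nodata in the sidecar instead
    }
    na_cells <- lapply(r$bands, function(b) which(is.na(b)))
    tiff::writeTIFF(arr, path, bits.per.sample = 32L)
    meta <- list(cell_size_m = r$cell_size_m, origin = r$origin,
                 role = r$role, band_names = names(r$bands),
                 lo = as.list(lo), span = as.list(span),
                 na_cells = na_cells, crs = r$crs)
    jsonlite::write_json(meta, paste0(path, ".aux.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  } else if (ext == "asc") {
    if (n_bands(r) != 1L)
      abort("ESRI ASCII grids are single-band; raster has %d bands",
            n_bands(r))
    m <- r$bands[[1]]
    nodata <- -9999
    m[is.na(m)] <- nodata
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      sprintf("ncols %d", ncol(m)),
      sprintf("nrows %d", nrow(m)),
      sprintf("xllcorner %.10g", r$origin[1]),
      sprintf("yllcorner %.10g", r$origin[2] - nrow(m) * r$cell_size_m),
      sprintf("cellsize %.10g", r$cell_size_m),
      sprintf("NODATA_value %d", nodata)), con)
    write.table(format(m, digits = 10, scientific = FALSE, trim = TRUE),
                con, row.names = FALSE, col.names = FALSE,
                quote = FALSE)
  } else {
    abort("unsupported raster format '.%s' (use .tif/.tiff or .asc)", ext)
  }
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) abort("raster file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    aux <- paste0(path, ".aux.json")
    if (!file.exists(aux))
      abort("missing sidecar %s (required field: cell_size_m)", aux)
    meta <- jsonlite::read_json(aux, simplifyVector = TRUE)
    arr <- tiff::readTIFF(path)
    if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
    nb <- dim(arr)[3]
    if (nb != length(meta$band_names))
      abort("malformed raster %s: %d bands on disk, sidecar names %d",
            path, nb, length(meta$band_names))
    bands <- vector("list", nb)
    for (b in seq_len(nb)) {
      m <- arr[, , b] * meta$span[[b]] + meta$lo[[b]]
      nas <- meta$na_cells[[b]]
      if (length(nas)) m[nas] <- NA_real_
      bands[[b]] <- m
    }
    canopy_raster(bands, meta$cell_size_m, unlist(meta$origin),
                  role = meta$role, band_names = meta$band_names,
                  crs = meta$crs)
  } else if (ext == "asc") {
    hdr <- readLines(path, n = 6L)
    kv <- strsplit(trimws(hdr), "\\s+")
    keys <- tolower(vapply(kv, `[`, "", 1L))
    vals <- as.numeric(vapply(kv, `[`, "", 2L))
    need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
    miss <- setdiff(need, keys)
    if (length(miss))
      abort("malformed ASCII grid %s: missing header field '%s'",
            path, miss[1])
    g <- setNames(vals, keys)
    m <- as.matrix(read.table(path, skip = length(hdr)))
    dimnames(m) <- NULL
    if (!all(dim(m) == c(g["nrows"], g["ncols"])))
      abort("malformed ASCII grid %s: data block does not match header",
            path)
    if ("nodata_value" %in% keys) m[m == g["nodata_value"]] <- NA_real_
    canopy_raster(m, g[["cellsize"]],
                  c(g[["xllcorner"]],
                    g[["yllcorner"]] + g[["nrows"]] * g[["cellsize"]]))
  } else {
    abort("unsupported raster format '.%s' (use .tif/.tiff or .asc)", ext)
  }
}

#' Read and write point clouds (ASCII XYZ)
#'
#' Point clouds are plain data frames with columns `x`, `y`, `z` (meters),
#' `return_number` (>= 1) and optionally logical `ground`.  On disk they
#' are CSV files with header `x,y,z,return_number[,ground]`; coordinates
#' are written with enough digits to roundtrip below 1 mm.
#'
#' @param cloud a point-cloud data frame.
#' @param path CSV file path (`.xyz` or `.csv`).
#' @return `read_point_cloud` returns the data frame; `write_point_cloud`
#'   returns `path` invisibly.
#' @export
write_point_cloud <- function(cloud, path) {
  validate_point_cloud(cloud)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("xyz", "csv"))
    abort("unsupported point-cloud format '.%s' (use .xyz or .csv)", ext)
  out <- cloud
  for (col in c("x", "y", "z"))
    out[[col]] <- formatC(out[[col]], format = "f", digits = 4)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_point_cloud
#' @export
read_point_cloud <- function(path) {
  if (!file.exists(path)) abort("point-cloud file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("xyz", "csv"))
    abort("unsupported point-cloud format '.%s' (use .xyz or .csv)", ext)
  d <- read.csv(path)
  need <- c("x", "y", "z")
  miss <- setdiff(need, names(d))
  if (length(miss))
    abort("malformed point cloud %s: missing column '%s'", path, miss[1])
  if (!"return_number" %in% names(d)) d$return_number <- 1L
  bad <- which(!complete.cases(d[need]) |
                 !apply(sapply(d[need], is.finite), 1, all))
  if (length(bad))
    abort("non-finite coordinates in %s at row %d", path, bad[1])
  if ("ground" %in% names(d)) d$ground <- as.logical(d$ground)
  validate_point_cloud(d)
  d
}

validate_point_cloud <- function(cloud) {
  if (!is.data.frame(cloud) ||
      !all(c("x", "y", "z") %in% names(cloud)))
    abort("a point cloud needs columns x, y, z")
  if (!nrow(cloud)) return(invisible(cloud))
  if (!all(vapply(cloud[c("x", "y", "z")],
                  function(v) all(is.finite(v)), logical(1))))
    abort("point cloud has non-finite coordinates")
  if ("return_number" %in% names(cloud) &&
      any(cloud$return_number < 1))
    abort("return_number must be >= 1")
  invisible(cloud)
}

#' Polygon sets and GeoJSON I/O
#'
#' A `polygon_set` is a list of crown outlines in map coordinates, each a
#' list with `id`, optional `species` and a two-column `coords` matrix
#' (one ring, stored open; rings are closed on write).  Serialised as a
#' GeoJSON FeatureCollection.
#'
#' @param polygons list of lists with fields `id`, `coords` and
#'   optionally `species`.
#' @return an object of class `polygon_set`.
#' @export
polygon_set <- function(polygons = list()) {
  for (p in polygons) {
    if (is.null(p$id) || is.null(p$coords) || !is.matrix(p$coords) ||
        ncol(p$coords) != 2L || nrow(p$coords) < 3L)
      abort("each polygon needs an `id` and a ring of >= 3 xy vertices")
  }
  ids <- vapply(polygons, function(p) as.character(p$id), "")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    abort("duplicate polygon ids: %s", paste(dup, collapse = ", "))
  structure(list(polygons = polygons), class = "polygon_set")
}

#' @export
length.polygon_set <- function(x) length(x$polygons)

#' @export
print.polygon_set <- function(x, ...) {
  cat(sprintf("<polygon_set> %d polygon(s)\n", length(x)))
  invisible(x)
}

#' Planar polygon area by the shoelace formula
#' @param coords two-column matrix of ring vertices (open or closed).
#' @return area in squared map units.
#' @export
polygon_area <- function(coords) {
  x <- coords[, 1]; y <- coords[, 2]
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' @param pset a [polygon_set].
#' @param path GeoJSON file path.
#' @rdname polygon_set
#' @export
write_polygons <- function(pset, path) {
  stopifnot(inherits(pset, "polygon_set"))
  features <- lapply(pset$polygons, function(p) {
    ring <- rbind(p$coords, p$coords[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(id = p$id, species = p$species),
         geometry = list(
           type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(ring)), function(i)
             as.numeric(ring[i, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname polygon_set
#' @export
read_polygons <- function(path) {
  if (!file.exists(path)) abort("polygon file not found: %s", path)
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    abort("malformed GeoJSON %s: expected a FeatureCollection", path)
  polys <- lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    coords <- do.call(rbind, lapply(ring, function(v)
      c(v[[1]], v[[2]])))
    n <- nrow(coords)
    if (all(coords[1, ] == coords[n, ]))
      coords <- coords[-n, , drop = FALSE]
    list(id = f$properties$id, species = f$properties$species,
         coords = coords)
  })
  polygon_set(polys)
}

#' Read and write field mensuration tables
#'
#' CSV tables with one row per measured tree: `tree_id`, `x_m`, `y_m`,
#' `species`, `dbh_cm`, `height_m`, `crown_width_m`.  Optional columns
#' may be absent; `tree_id` must be unique and measurements positive.
#'
#' @param path CSV file path.
#' @param table field table data frame (for writing).
#' @return `read_field_table` returns a data frame.
#' @export
read_field_table <- function(path) {
  if (!file.exists(path)) abort("field table not found: %s", path)
  d <- read.csv(path)
  if (!"tree_id" %in% names(d))
    abort("malformed field table %s: missing column 'tree_id'", path)
  dup <- unique(d$tree_id[duplicated(d$tree_id)])
  if (length(dup))
    abort("duplicated tree_id in %s: %s", path,
          paste(dup, collapse = ", "))
  for (col in intersect(c("dbh_cm", "height_m", "crown_width_m"), names(d)))
    if (any(d[[col]] <= 0, na.rm = TRUE))
      abort("non-positive %s in %s", col, path)
  d
}

#' @rdname read_field_table
#' @export
write_field_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}
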