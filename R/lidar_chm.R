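#' Ground-filter parameters
#'
#' Controls the iterative ground-point classifier, a locally weighted
#' plane-fit approximation of the classic linear-prediction ground
#' filter: after seeding a surface from per-cell lowest points, each
#' iteration reweights every return by its residual above the current
#' surface (`w = 1` for residuals at most `g`; `w = 1 / (1 + (a (r - g))^b)`
#' above) and refits local planes on a coarse grid, pulling the surface
#' to the ground while vegetation returns lose influence.  Three
#' iterations suffice on the point densities used here.
#'
#' @param n_iterations number of reweighting iterations (>= 1).
#' @param seed_cell_m coarse-grid cell size (m) for lowest-point seeding
#'   and plane fitting.
#' @param a,b weight-function shape parameters (> 0).
#' @param g below-surface shift (m): residuals up to `g` keep weight 1.
#' @param tolerance residual tolerance (m): returns within `tolerance`
#'   of the final surface are flagged ground.
#' @return list of class `ground_filter_params`.
#' @export
ground_filter_params <- function(n_iterations = 3L, seed_cell_m = 5,
                                 a = 1, b = 4, g = 0.05, tolerance = 0.3) {
  if (n_iterations < 1) abort("`n_iterations` must be >= 1")
  check_scalar(a, "a", positive = TRUE)
  check_scalar(b, "b", positive = TRUE)
  check_scalar(tolerance, "tolerance", positive = TRUE)
  check_scalar(seed_cell_m, "seed_cell_m", positive = TRUE)
  structure(list(n_iterations = as.integer(n_iterations),
                 seed_cell_m = seed_cell_m, a = a, b = b, g = g,
                 tolerance = tolerance), class = "ground_filter_params")
}

#' Classify ground returns in a point cloud
#'
#' Flags the probable ground points of a discrete-return cloud using the
#' iterative weighted plane-fit scheme described in
#' [ground_filter_params()].  On a noiseless plane every point is
#' flagged ground; canopy returns tens of meters above the surface
#' receive vanishing weight and are excluded.
#'
#' @param cloud point-cloud data frame (`x`, `y`, `z`).
#' @param params a [ground_filter_params()] object.
#' @return the cloud with a logical `ground` column.
#' @export
classify_ground <- function(cloud, params = ground_filter_params()) {
  validate_point_cloud(cloud)
  if (nrow(cloud) < 3L)
    abort("ground filtering needs at least 3 points (got %d)", nrow(cloud))
  if (qr(cbind(1, cloud$x, cloud$y))$rank < 3L)
    abort("degenerate point cloud: xy coordinates are collinear")

  cell <- params$seed_cell_m
  x0 <- min(cloud$x); y0 <- min(cloud$y)
  nc <- max(1L, ceiling((max(cloud$x) - x0) / cell))
  nr <- max(1L, ceiling((max(cloud$y) - y0) / cell))
  ci <- pmin(floor((cloud$x - x0) / cell) + 1L, nc)
  ri <- pmin(floor((cloud$y - y0) / cell) + 1L, nr)
  cell_id <- (ci - 1L) * nr + ri
  pts_by_cell <- split(seq_len(nrow(cloud)), cell_id)

  # coefficient grids: z = c0 + cx * (x - xc) + cy * (y - yc)
  c0 <- matrix(NA_real_, nr, nc); cx <- matrix(0, nr, nc)
  cy <- matrix(0, nr, nc)
  seed_min <- matrix(NA_real_, nr, nc)
  for (k in names(pts_by_cell)) {
    id <- as.integer(k)
    seed_min[id] <- min(cloud$z[pts_by_cell[[k]]])
  }
  c0 <- fill_na_neighbours(seed_min)

  eval_surface <- function() {
    xc <- x0 + (ci - 0.5) * cell
    yc <- y0 + (ri - 0.5) * cell
    idx <- cbind(ri, ci)
    c0[idx] + cx[idx] * (cloud$x - xc) + cy[idx] * (cloud$y - yc)
  }

  w <- rep(1, nrow(cloud))
  for (iter in seq_len(params$n_iterations)) {
    r <- cloud$z - eval_surface()
    w <- ifelse(r <= params$g, 1,
                1 / (1 + (params$a * (r - params$g))^params$b))
    new_c0 <- matrix(NA_real_, nr, nc)
    new_cx <- matrix(0, nr, nc); new_cy <- matrix(0, nr, nc)
    for (cc in seq_len(nc)) {
      for (rr in seq_len(nr)) {
        nb_cells <- as.character(
          outer((max(1, rr - 1):min(nr, rr + 1)),
                (max(1, cc - 1):min(nc, cc + 1)) - 1L, function(r, c)
                  c * nr + r))
        ids <- unlist(pts_by_cell[nb_cells], use.names = FALSE)
        if (is.null(ids) || !length(ids)) next
        wi <- w[ids]
        if (sum(wi) < 1e-9) next
        xc <- x0 + (cc - 0.5) * cell; yc <- y0 + (rr - 0.5) * cell
        X <- cbind(1, cloud$x[ids] - xc, cloud$y[ids] - yc)
        XtW <- t(X * wi)
        fit <- tryCatch(
          solve(XtW %*% X + diag(1e-8, 3), XtW %*% cloud$z[ids]),
          error = function(e) NULL)
        if (is.null(fit) || !all(is.finite(fit))) {
          new_c0[rr, cc] <- sum(wi * cloud$z[ids]) / sum(wi)
        } else {
          new_c0[rr, cc] <- fit[1]
          new_cx[rr, cc] <- fit[2]
          new_cy[rr, cc] <- fit[3]
        }
      }
    }
    c0 <- fill_na_neighbours(new_c0)
    cx <- new_cx; cy <- new_cy
  }
  cloud$ground <- (cloud$z - eval_surface()) <= params$tolerance
  cloud
}

#' Gridding parameters
#'
#' @param cell_size_m output cell size (m).
#' @param aggregator `"mean"` (terrain models) or `"max"` (surface
#'   models) of the point elevations per cell.
#' @param fill `"nearest"` fills empty cells from their nearest occupied
#'   neighbours (iterative dilation), `"nodata"` leaves them `NA`.
#' @return list of class `grid_params`.
#' @export
grid_params <- function(cell_size_m = 0.5,
                        aggregator = c("mean", "max"),
                        fill = c("nearest", "nodata")) {
  check_scalar(cell_size_m, "cell_size_m", positive = TRUE)
  structure(list(cell_size_m = cell_size_m,
                 aggregator = match.arg(aggregator),
                 fill = match.arg(fill)), class = "grid_params")
}

#' Project a point cloud onto a 2-D grid
#'
#' Each grid cell takes the aggregator (mean or max) of the elevations
#' of the points falling in it; empty cells follow the fill policy.  The
#' conventional products are a DSM (`aggregator = "max"` over all
#' returns, `fill = "nodata"`) and a DTM (`aggregator = "mean"` over
#' ground-flagged points, `fill = "nearest"`, ground being continuous).
#'
#' @param cloud point-cloud data frame.
#' @param params a [grid_params()] object.
#' @param subset `"all"`, `"ground"` (requires a `ground` column) or
#'   `"first_return"`.
#' @param geometry optional list `(origin, nrow, ncol)` fixing the output
#'   grid; defaults to the cloud's bounding box snapped to whole cells.
#' @param role role tag of the returned raster.
#' @return a single-band [canopy_raster].
#' @export
grid_points <- function(cloud, params = grid_params(),
                        subset = c("all", "ground", "first_return"),
                        geometry = NULL, role = "dsm") {
  validate_point_cloud(cloud)
  subset <- match.arg(subset)
  if (!nrow(cloud)) abort("empty point cloud")
  keep <- switch(subset,
    all = rep(TRUE, nrow(cloud)),
    ground = {
      if (!"ground" %in% names(cloud))
        abort("subset='ground' needs a ground flag; run classify_ground()")
      cloud$ground
    },
    first_return = cloud$return_number == 1L)
  pts <- cloud[keep, , drop = FALSE]
  if (!nrow(pts)) abort("no points left after subset '%s'", subset)
  cell <- params$cell_size_m
  if (is.null(geometry)) {
    x0 <- floor(min(pts$x) / cell) * cell
    y1 <- ceiling(max(pts$y) / cell) * cell
    ncl <- max(1L, ceiling((max(pts$x) - x0) / cell))
    nrw <- max(1L, ceiling((y1 - min(pts$y)) / cell))
    geometry <- list(origin = c(x0, y1), nrow = nrw, ncol = ncl)
  }
  nrw <- geometry$nrow; ncl <- geometry$ncol
  col <- floor((pts$x - geometry$origin[1]) / cell) + 1L
  row <- floor((geometry$origin[2] - pts$y) / cell) + 1L
  inside <- col >= 1L & col <= ncl & row >= 1L & row <= nrw
  if (!any(inside))
    abort("no points fall inside the requested grid extent")
  idx <- (col[inside] - 1L) * nrw + row[inside]
  z <- pts$z[inside]
  m <- matrix(NA_real_, nrw, ncl)
  if (params$aggregator == "mean") {
    sums <- rowsum(z, idx)
    cnts <- rowsum(rep(1, length(z)), idx)
    m[as.integer(rownames(sums))] <- sums / cnts
  } else {
    o <- order(idx, z)                 # last per group = max
    last <- o[c(diff(idx[o]) != 0, TRUE)]
    m[idx[last]] <- z[last]
  }
  if (params$fill == "nearest") m <- fill_na_neighbours(m)
  canopy_raster(m, cell, origin = geometry$origin, role = role,
                band_names = "elevation")
}

#' 3 x 3 median filter
#'
#' Replaces every cell by the median of its up-to-9-cell neighbourhood;
#' edge cells use the neighbours that exist and nodata cells are
#' excluded from windows (and stay nodata themselves).  Used to smooth
#' the gridded ground surface, whose raw cell values change abruptly
#' where ground returns are sparse.
#'
#' @param r a single-band [canopy_raster].
#' @return filtered raster of the same geometry.
#' @export
median_filter3 <- function(r) {
  stopifnot(inherits(r, "canopy_raster"))
  if (n_bands(r) != 1L) abort("median_filter3 expects a single band")
  m <- r$bands[[1]]
  nr <- nrow(m); nc <- ncol(m)
  stack <- matrix(NA_real_, nr * nc, 9L)
  k <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    k <- k + 1L
    sh <- matrix(NA_real_, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    okr <- rs >= 1L & rs <= nr; okc <- cs >= 1L & cs <= nc
    sh[okr, okc] <- m[rs[okr], cs[okc]]
    stack[, k] <- sh
  }
  med <- apply(stack, 1L, median, na.rm = TRUE)
  med[is.na(m)] <- NA_real_       # nodata cells stay nodata
  out <- r
  out$bands[[1]] <- matrix(med, nr, nc)
  out
}

#' Canopy height model from surface and terrain models
#'
#' `CHM = DSM - DTM`, with negative differences clamped to zero
#' (physical heights) and nodata propagating from either input.  The two
#' rasters must be aligned.
#'
#' @param dsm,dtm single-band [canopy_raster]s on the same grid.
#' @return a [canopy_raster] with role `"chm"`.
#' @export
compute_chm <- function(dsm, dtm) {
  stopifnot(inherits(dsm, "canopy_raster"), inherits(dtm, "canopy_raster"))
  if (!same_geometry(dsm, dtm))
    abort("misaligned grids: DSM is %s but DTM is %s",
          geometry_string(dsm), geometry_string(dtm))
  chm <- pmax(dsm$bands[[1]] - dtm$bands[[1]], 0)
  canopy_raster(chm, dsm$cell_size_m, dsm$origin, role = "chm",
                band_names = "height")
}

#' Full point-cloud to CHM workflow
#'
#' Convenience wrapper: classify ground, grid the DTM (mean of ground
#' returns, nearest-fill, then 3 x 3 median filter), grid the DSM (max of
#' all returns, nearest-fill) and subtract.
#'
#' @param cloud point-cloud data frame.
#' @param cell_size_m output grid cell (m).
#' @param gf_params a [ground_filter_params()] object.
#' @param geometry optional grid geometry (see [grid_points()]).
#' @return list with `dtm`, `dsm`, `chm` rasters and the flagged cloud.
#' @export
chm_workflow <- function(cloud, cell_size_m = 0.5,
                         gf_params = ground_filter_params(),
                         geometry = NULL) {
  flagged <- classify_ground(cloud, gf_params)
  dtm <- grid_points(flagged, grid_params(cell_size_m, "mean", "nearest"),
                     subset = "ground", geometry = geometry, role = "dtm")
  if (is.null(geometry))
    geometry <- list(origin = dtm$origin, nrow = nrow(dtm$bands[[1]]),
                     ncol = ncol(dtm$bands[[1]]))
  dtm <- median_filter3(dtm)
  dsm <- grid_points(flagged, grid_params(cell_size_m, "max", "nearest"),
                     subset = "all", geometry = geometry, role = "dsm")
  list(dtm = dtm, dsm = dsm, chm = compute_chm(dsm, dtm),
       cloud = flagged)
}
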