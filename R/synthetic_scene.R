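#' Species tables for synthetic scenes
#'
#' A species table describes the canopy species a synthetic scene can
#' contain: per-band spectral means (8-bit digital numbers), a spectral
#' standard deviation, per-band texture roughness in `[0, 1]`, and the
#' height and crown-width ranges trees of the species are drawn from.
#' Roughness is the amplitude of an additional spatially correlated
#' brightness field (sunlit and self-shadowed foliage clumps) laid over
#' the white sensor-scale speckle: rough canopies show broader, clumpier
#' tonal distributions at identical mean spectra, so species differing
#' only in roughness share a mean signature but differ in local texture.
#'
#' `default_species()` gives five canopy species with overlapping
#' spectral means — the low spectral separability typical of tropical
#' canopies.  `separable_species()` spreads the means at least three
#' standard deviations apart.  `texture_pair_species()` returns two
#' species with identical spectra whose red-band roughness differs, so
#' only texture can tell them apart.
#'
#' @return data frame with columns `species`, `mean_r`, `mean_g`,
#'   `mean_b`, `spectral_sd`, `rough_r`, `rough_g`, `rough_b`,
#'   `height_min`, `height_max`, `width_min`, `width_max`.
#' @export
default_species <- function() {
  data.frame(
    species = c("A", "B", "C", "D", "E"),
    mean_r = c(62, 74, 68, 83, 66),
    mean_g = c(110, 96, 119, 104, 100),
    mean_b = c(56, 50, 64, 60, 74),
    spectral_sd = 8,
    rough_r = c(0.15, 0.3, 0.2, 0.45, 0.25),
    rough_g = c(0.15, 0.25, 0.2, 0.4, 0.25),
    rough_b = c(0.1, 0.2, 0.15, 0.3, 0.2),
    height_min = c(28, 25, 26, 25, 25),
    height_max = c(40, 35, 38, 33, 36),
    width_min = c(12, 8, 10, 8, 9),
    width_max = c(25, 18, 22, 16, 20))
}

#' @rdname default_species
#' @export
separable_species <- function() {
  sp <- default_species()
  # means >= 3 spectral sd apart pairwise (sd = 8 -> min distance 24)
  sp$mean_r <- c(40, 90, 40, 140, 90)
  sp$mean_g <- c(120, 70, 60, 110, 130)
  sp$mean_b <- c(50, 60, 110, 70, 100)
  sp
}

#' @rdname default_species
#' @export
texture_pair_species <- function() {
  sp <- default_species()[1:2, ]
  sp$species <- c("smooth", "rough")
  sp$mean_r <- 70; sp$mean_g <- 105; sp$mean_b <- 58
  sp$rough_r <- c(0.05, 0.85)
  sp$rough_g <- 0.15; sp$rough_b <- 0.15
  sp$height_min <- 25; sp$height_max <- 38
  sp$width_min <- 9; sp$width_max <- 20
  sp
}

#' Parameters of a synthetic forest scene
#'
#' Defaults describe the desk-scale study conditions used throughout the
#' package: a 200 x 200 m stand of 25 canopy trees from five species,
#' tree heights 25-40 m, crown widths ~8-25 m, imagery at 0.5 m pixels
#' (8-bit RGB) and a discrete-return point cloud at 12 returns per m^2
#' over flat-to-gently-undulating terrain.
#'
#' @param extent_m scene width/height in meters.
#' @param cell_size_m imagery resolution (m/pixel).
#' @param n_trees number of trees to place.
#' @param species_table see [default_species()].
#' @param point_density LiDAR returns per m^2.
#' @param terrain named vector `(base, slope, undulation)`: base elevation
#'   (m), linear slope along x (m/m), amplitude (m) of a smooth sinusoidal
#'   undulation with an 80 m wavelength.
#' @param noise_sd sensor noise added to every image band (DN).
#' @param seed integer seed; all outputs are pure functions of
#'   (params, seed).
#' @param min_spacing_factor stems must be at least this multiple of the
#'   mean of the two crowns' major axes apart; the default 1.1 yields
#'   disjoint crowns, values < 1 allow overlap.
#' @param canopy_gap_fraction fraction of pulses over a crown that
#'   penetrate to the ground.
#' @param crown_depth_fraction vertical depth of the paraboloid crown cap
#'   as a fraction of tree height.
#' @param background_dn,background_sd bare-ground spectrum (DN) and noise.
#' @param roughness_dn full-scale amplitude (DN) of the correlated
#'   roughness field; a species' per-band roughness multiplies it.
#' @param roughness_sigma_px correlation length (pixels) of the
#'   roughness field.
#' @return a list of class `scene_params`.
#' @export
scene_params <- function(extent_m = 200, cell_size_m = 0.5, n_trees = 25,
                         species_table = default_species(),
                         point_density = 12,
                         terrain = c(base = 50, slope = 0.001,
                                     undulation = 0.2),
                         noise_sd = 2, seed = 1,
                         min_spacing_factor = 1.1,
                         canopy_gap_fraction = 0.15,
                         crown_depth_fraction = 0.35,
                         background_dn = c(150, 140, 125),
                         background_sd = 5, roughness_dn = 35,
                         roughness_sigma_px = 1.5) {
  check_scalar(extent_m, "extent_m", positive = TRUE)
  check_scalar(cell_size_m, "cell_size_m", positive = TRUE)
  check_scalar(point_density, "point_density", positive = TRUE)
  if (!is.numeric(n_trees) || n_trees < 0)
    abort("`n_trees` must be >= 0")
  st <- species_table
  need <- c("species", "mean_r", "mean_g", "mean_b", "spectral_sd",
            "rough_r", "rough_g", "rough_b", "height_min", "height_max",
            "width_min", "width_max")
  miss <- setdiff(need, names(st))
  if (length(miss))
    abort("species_table is missing column '%s'", miss[1])
  if (any(st$height_min > st$height_max) ||
      any(st$width_min > st$width_max))
    abort("species_table ranges must have min <= max")
  dn <- unlist(st[c("mean_r", "mean_g", "mean_b")])
  if (any(dn < 0 | dn > 255))
    abort("spectral means must lie within [0, 255]")
  structure(list(extent_m = extent_m, cell_size_m = cell_size_m,
                 n_trees = as.integer(n_trees), species_table = st,
                 point_density = point_density, terrain = terrain,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 min_spacing_factor = min_spacing_factor,
                 canopy_gap_fraction = canopy_gap_fraction,
                 crown_depth_fraction = crown_depth_fraction,
                 background_dn = background_dn,
                 background_sd = background_sd,
                 roughness_dn = roughness_dn,
                 roughness_sigma_px = roughness_sigma_px),
            class = "scene_params")
}

# terrain elevation at map coordinates
terrain_z <- function(terrain, x, y) {
  terrain[["base"]] + terrain[["slope"]] * x +
    terrain[["undulation"]] * sin(2 * pi * x / 80) * cos(2 * pi * y / 80)
}

# paraboloid crown surface height above terrain-at-stem; NA outside crown
crown_rho2 <- function(crown, x, y) {
  dx <- x - crown$x; dy <- y - crown$y
  u <- cos(crown$rot) * dx + sin(crown$rot) * dy
  v <- -sin(crown$rot) * dx + cos(crown$rot) * dy
  (u / (crown$axis_major_m / 2))^2 + (v / (crown$axis_minor_m / 2))^2
}

# sample tree placements honouring the minimum stem spacing
place_trees <- function(params) {
  st <- params$species_table
  n <- params$n_trees
  if (n == 0L)
    return(data.frame(tree_id = integer(), species = character(),
                      x = numeric(), y = numeric(),
                      axis_major_m = numeric(), axis_minor_m = numeric(),
                      rot = numeric(), height_m = numeric(),
                      crown_width_m = numeric()))
  sp_idx <- sample(rep_len(seq_len(nrow(st)), n))
  width <- runif(n, st$width_min[sp_idx], st$width_max[sp_idx])
  ratio <- runif(n, 0.8, 1)
  # crown width is the mean of the two perpendicular axis lengths
  axis_minor <- 2 * width / (1 + 1 / ratio)
  axis_major <- axis_minor / ratio
  rot <- runif(n, 0, pi)
  height <- runif(n, st$height_min[sp_idx], st$height_max[sp_idx])
  inset <- axis_major / 2
  if (any(2 * inset >= params$extent_m))
    abort("extent_m too small for the largest crown axis")
  xs <- ys <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(500L)) {
      cx <- runif(1, inset[i], params$extent_m - inset[i])
      cy <- runif(1, inset[i], params$extent_m - inset[i])
      if (i == 1L) { placed <- TRUE }
      else {
        j <- seq_len(i - 1L)
        mind <- params$min_spacing_factor *
          (axis_major[i] + axis_major[j]) / 2
        placed <- all((cx - xs[j])^2 + (cy - ys[j])^2 >= mind^2)
      }
      if (placed) { xs[i] <- cx; ys[i] <- cy; break }
    }
    if (!placed)
      abort(paste0("could not place %d trees in a %g m extent without ",
                   "violating the minimum stem spacing ",
                   "(min_spacing_factor = %g)"),
            n, params$extent_m, params$min_spacing_factor)
  }
  data.frame(tree_id = seq_len(n), species = st$species[sp_idx],
             x = xs, y = ys, axis_major_m = axis_major,
             axis_minor_m = axis_minor, rot = rot, height_m = height,
             crown_width_m = (axis_major + axis_minor) / 2)
}

#' Generate a synthetic forest scene
#'
#' Builds a scene with the statistical structure the downstream analysis
#' assumes: 8-bit RGB imagery in which crown pixels are drawn from the
#' species' spectral distribution plus a spatially correlated roughness
#' field, a discrete-return point cloud whose ground returns follow the
#' terrain and whose canopy returns follow paraboloid crown envelopes at
#' the requested density, and a ground-truth record of every placed
#' crown.  Identical parameters and seed give bit-identical outputs.
#'
#' @param params a [scene_params()] object.
#' @return list with `imagery` (a [canopy_raster]), `cloud` (point-cloud
#'   data frame) and `truth` (class `scene_truth`: data frame `crowns`,
#'   the terrain parameters and scene extent).
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  with_seed(params$seed, {
    crowns <- place_trees(params)
    npx <- round(params$extent_m / params$cell_size_m)
    st <- params$species_table
    xs <- (seq_len(npx) - 0.5) * params$cell_size_m
    ys <- params$extent_m - (seq_len(npx) - 0.5) * params$cell_size_m

    bands <- lapply(1:3, function(b)
      matrix(params$background_dn[b] + rnorm(npx * npx,
                                             sd = params$background_sd),
             npx, npx))
    rough_field <- lapply(1:3, function(b) {
      f <- gaussian_smooth(matrix(rnorm(npx * npx), npx, npx),
                           params$roughness_sigma_px)
      (f - mean(f)) / sd(f)
    })

    surface <- matrix(-Inf, npx, npx)  # crown surface height, ownership
    owner <- matrix(0L, npx, npx)
    for (i in seq_len(nrow(crowns))) {
      cr <- crowns[i, ]
      half <- cr$axis_major_m / 2
      cidx <- which(xs >= cr$x - half & xs <= cr$x + half)
      ridx <- which(ys >= cr$y - half & ys <= cr$y + half)
      if (!length(cidx) || !length(ridx)) next
      g <- expand.grid(r = ridx, c = cidx)
      rho2 <- crown_rho2(cr, xs[g$c], ys[g$r])
      inside <- rho2 <= 1
      if (!any(inside)) next
      z <- terrain_z(params$terrain, cr$x, cr$y) + cr$height_m -
        params$crown_depth_fraction * cr$height_m * rho2
      sel <- cbind(g$r, g$c)[inside, , drop = FALSE]
      zin <- z[inside]
      take <- zin > surface[sel]
      if (!any(take)) next
      surface[sel[take, , drop = FALSE]] <- zin[take]
      owner[sel[take, , drop = FALSE]] <- i
    }
    sp_row <- match(crowns$species, st$species)
    means <- as.matrix(st[c("mean_r", "mean_g", "mean_b")])
    roughs <- as.matrix(st[c("rough_r", "rough_g", "rough_b")])
    crown_px <- which(owner > 0L)
    for (b in 1:3) {
      own <- owner[crown_px]
      bands[[b]][crown_px] <-
        means[sp_row[own], b] +
        rnorm(length(crown_px), sd = st$spectral_sd[sp_row[own]]) +
        rough_field[[b]][crown_px] * roughs[sp_row[own], b] *
          params$roughness_dn
    }
    for (b in 1:3) {
      m <- bands[[b]] + rnorm(npx * npx, sd = params$noise_sd)
      bands[[b]] <- matrix(pmin(pmax(round(m), 0), 255), npx, npx)
    }
    imagery <- canopy_raster(bands, params$cell_size_m,
                             origin = c(0, params$extent_m),
                             role = "imagery",
                             band_names = c("red", "green", "blue"))

    # ---- point cloud ----
    n_pts <- round(params$point_density * params$extent_m^2)
    px <- runif(n_pts, 0, params$extent_m)
    py <- runif(n_pts, 0, params$extent_m)
    pz <- terrain_z(params$terrain, px, py) + rnorm(n_pts, sd = 0.03)
    ret <- rep(1L, n_pts)
    if (nrow(crowns)) {
      hit <- rep(0L, n_pts)       # owning crown per pulse
      hit_z <- rep(-Inf, n_pts)
      for (i in seq_len(nrow(crowns))) {
        cr <- crowns[i, ]
        half <- cr$axis_major_m / 2
        cand <- which(abs(px - cr$x) <= half & abs(py - cr$y) <= half)
        if (!length(cand)) next
        rho2 <- crown_rho2(cr, px[cand], py[cand])
        inside <- cand[rho2 <= 1]
        if (!length(inside)) next
        z <- terrain_z(params$terrain, cr$x, cr$y) + cr$height_m -
          params$crown_depth_fraction * cr$height_m * rho2[rho2 <= 1]
        take <- z > hit_z[inside]
        hit[inside[take]] <- i
        hit_z[inside[take]] <- z[take]
      }
      under <- which(hit > 0L)
      canopy <- under[runif(length(under)) > params$canopy_gap_fraction]
      pz[canopy] <- hit_z[canopy] + rnorm(length(canopy), sd = 0.1)
      ret[setdiff(under, canopy)] <- 2L  # ground hit beneath canopy
    }
    cloud <- data.frame(x = px, y = py, z = pz, return_number = ret)

    truth <- structure(list(crowns = crowns, terrain = params$terrain,
                            extent_m = params$extent_m,
                            cell_size_m = params$cell_size_m),
                       class = "scene_truth")
    list(imagery = imagery, cloud = cloud, truth = truth)
  })
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %d crowns over %g x %g m\n",
              nrow(x$crowns), x$extent_m, x$extent_m))
  invisible(x)
}

#' Reference crown polygons from scene truth
#'
#' Converts each true crown ellipse to a 64-gon outline, the synthetic
#' stand-in for manually digitised reference crowns.  Polygon areas match
#' the exact ellipse areas to within 0.2%.
#'
#' @param truth a `scene_truth` object.
#' @param n_vertices vertices per outline.
#' @return a [polygon_set] with one polygon per crown, `id = tree_id`.
#' @export
truth_to_reference_polygons <- function(truth, n_vertices = 64L) {
  stopifnot(inherits(truth, "scene_truth"))
  theta <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  polys <- lapply(seq_len(nrow(truth$crowns)), function(i) {
    cr <- truth$crowns[i, ]
    u <- (cr$axis_major_m / 2) * cos(theta)
    v <- (cr$axis_minor_m / 2) * sin(theta)
    coords <- cbind(cr$x + cos(cr$rot) * u - sin(cr$rot) * v,
                    cr$y + sin(cr$rot) * u + cos(cr$rot) * v)
    list(id = cr$tree_id, species = cr$species, coords = coords)
  })
  polygon_set(polys)
}

#' Simulated field mensuration table from scene truth
#'
#' Adds independent Gaussian measurement error to the true heights and
#' crown widths (field campaigns show low systematic but appreciable
#' random error) and derives DBH from a simple allometry on height and
#' crown width.  Zero error standard deviations reproduce the truth
#' exactly.
#'
#' @param truth a `scene_truth` object.
#' @param height_error_sd,width_error_sd measurement error (m), >= 0.
#' @param seed integer seed.
#' @return field-table data frame (`tree_id`, `x_m`, `y_m`, `species`,
#'   `dbh_cm`, `height_m`, `crown_width_m`).
#' @export
truth_field_table <- function(truth, height_error_sd = 0,
                              width_error_sd = 0, seed = 1) {
  stopifnot(inherits(truth, "scene_truth"))
  if (height_error_sd < 0 || width_error_sd < 0)
    abort("measurement error sds must be >= 0")
  cr <- truth$crowns
  with_seed(seed, {
    n <- nrow(cr)
    data.frame(
      tree_id = cr$tree_id, x_m = cr$x, y_m = cr$y,
      species = cr$species,
      dbh_cm = pmax(10, -30 + 2.2 * cr$height_m + 1.5 * cr$crown_width_m +
                      rnorm(n, sd = 6)),
      height_m = pmax(2, cr$height_m + rnorm(n, sd = height_error_sd)),
      crown_width_m = pmax(0.5, cr$crown_width_m +
                             rnorm(n, sd = width_error_sd)))
  })
}

#' Sample labelled pixels from true crowns
#'
#' Draws up to `per_crown` pixels from each true crown's footprint and
#' assembles a sample table (one row per pixel) of the raster stack's
#' band values labelled with the crown's species — the synthetic
#' analogue of training/validation pixels digitised around ground-located
#' trees.
#'
#' @param r a [canopy_raster] (imagery, optionally with texture bands
#'   appended via `extra`).
#' @param truth a `scene_truth` object.
#' @param per_crown maximum pixels sampled per crown.
#' @param seed integer seed.
#' @param extra optional further [canopy_raster] stacks (list) on the
#'   same grid whose bands are appended as features.
#' @return data frame of feature columns plus `class` (species) and
#'   `tree_id`.
#' @export
sample_crown_pixels <- function(r, truth, per_crown = 50L, seed = 1,
                                extra = NULL) {
  stopifnot(inherits(r, "canopy_raster"), inherits(truth, "scene_truth"))
  stacks <- c(list(r), if (!is.null(extra)) extra)
  for (s in stacks[-1])
    if (!same_geometry(s, r))
      abort("extra feature stacks must share the imagery grid")
  refs <- truth_to_reference_polygons(truth)
  px <- rasterize_polygons(refs, r)
  with_seed(seed, {
    rows <- lapply(seq_along(px), function(i) {
      id <- px[[i]]
      if (!length(id)) return(NULL)
      take <- if (length(id) > per_crown) sort(sample(id, per_crown))
              else id
      feat <- lapply(stacks, function(s)
        as.data.frame(lapply(s$bands, function(b) b[take])))
      d <- do.call(cbind, feat)
      d$class <- truth$crowns$species[i]
      d$tree_id <- truth$crowns$tree_id[i]
      d
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
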