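#' Segmentation parameters
#'
#' @param scale positive stopping threshold of the region-merging
#'   segmenter: merging stops once the cheapest mutual merge would cost
#'   at least `scale^2`.  Data-dependent; larger values give fewer,
#'   larger segments.
#' @param w_color weight of spectral (colour) heterogeneity in the
#'   fusion cost, in `[0, 1]`; the remainder weights shape.
#' @param w_compact within the shape term, weight of compactness versus
#'   smoothness, in `[0, 1]`.
#' @param band_weights per-band weights (>= 0, sum > 0); default equal.
#' @param min_segment_px segments smaller than this are dropped by
#'   [crown_metrics()].
#' @param gaussian_sigma_px watershed: Gaussian pre-smoothing in pixels.
#' @param h_frac watershed: minima/maxima shallower than this fraction
#'   of the image dynamic range are suppressed before flooding.
#' @param input watershed: flood the smoothed `"brightness"` surface
#'   directly (bright crowns become basins of the inverted relief) or
#'   its inverted Sobel `"gradient"` magnitude.
#' @return list of class `seg_params`.
#' @export
seg_params <- function(scale = 10, w_color = 0.9, w_compact = 0.5,
                       band_weights = NULL, min_segment_px = 10L,
                       gaussian_sigma_px = 2, h_frac = 0.05,
                       input = c("brightness", "gradient")) {
  check_scalar(scale, "scale", positive = TRUE)
  if (w_color < 0 || w_color > 1) abort("`w_color` must be in [0, 1]")
  if (w_compact < 0 || w_compact > 1)
    abort("`w_compact` must be in [0, 1]")
  if (!is.null(band_weights) &&
      (any(band_weights < 0) || sum(band_weights) <= 0))
    abort("`band_weights` must be >= 0 with positive sum")
  structure(list(scale = scale, w_color = w_color, w_compact = w_compact,
                 band_weights = band_weights,
                 min_segment_px = as.integer(min_segment_px),
                 gaussian_sigma_px = gaussian_sigma_px, h_frac = h_frac,
                 input = match.arg(input)), class = "seg_params")
}

# resolve a mask argument: logical matrix, or NULL -> all finite pixels
resolve_mask <- function(r, mask) {
  finite <- Reduce(`&`, lapply(r$bands, is.finite))
  if (is.null(mask)) return(finite)
  stopifnot(is.logical(mask), all(dim(mask) == dim(r)))
  mask & finite
}

#' Multiresolution (region-merging) crown segmentation
#'
#' Bottom-up object building: every unmasked pixel starts as its own
#' object and adjacent objects merge by local mutual best fitting — a
#' pair merges when each is the other's cheapest neighbour — while the
#' fusion cost stays below `scale^2`.  The cost mixes the growth of
#' n-weighted per-band standard deviation with shape regularity
#' (compactness and smoothness), so segments stay spectrally homogeneous
#' and spatially coherent.  Deterministic given its inputs, with ties
#' broken toward the lowest label.
#'
#' @param r a [canopy_raster] (imagery or CHM).
#' @param params a [seg_params()] object.
#' @param mask optional logical matrix: pixels to segment (e.g. canopy
#'   pixels from a CHM threshold).  Masked-out pixels become background
#'   label 0.
#' @return a [canopy_raster] with role `"segmentmap"` whose single band
#'   holds integer labels (0 = background, 1..K contiguous).
#' @export
multiresolution_segment <- function(r, params = seg_params(),
                                    mask = NULL) {
  stopifnot(inherits(r, "canopy_raster"), inherits(params, "seg_params"))
  m <- resolve_mask(r, mask)
  if (!any(m)) abort("all pixels are nodata or masked out")
  bw <- params$band_weights
  if (is.null(bw)) bw <- rep(1, n_bands(r))
  bw <- bw / sum(bw)
  bands <- do.call(cbind, lapply(r$bands, as.vector))
  bands[is.na(bands)] <- 0       # masked anyway
  labels <- .multires_cpp(bands, m, params$scale, params$w_color,
                          params$w_compact, as.numeric(bw))
  canopy_raster(labels, r$cell_size_m, r$origin, role = "segmentmap",
                band_names = "label")
}

#' Watershed crown segmentation
#'
#' Treats (inverted) image brightness as a topographic relief: after
#' Gaussian smoothing, bright crown apexes become basin bottoms, basins
#' shallower than `h_frac` of the dynamic range are suppressed, and the
#' relief is flooded; each surviving basin becomes one crown segment.
#' With `input = "gradient"` the inverted Sobel gradient magnitude is
#' flooded instead, so low-texture crown interiors form the basins.
#' The flooding itself is delegated to [EBImage::watershed()].
#'
#' @param r a [canopy_raster]; multiband input is reduced to mean
#'   brightness.
#' @param params a [seg_params()] object.
#' @param mask optional logical matrix of foreground pixels; background
#'   is labelled 0.
#' @return a [canopy_raster] with role `"segmentmap"` (labels as in
#'   [multiresolution_segment()]).
#' @export
watershed_segment <- function(r, params = seg_params(), mask = NULL) {
  stopifnot(inherits(r, "canopy_raster"), inherits(params, "seg_params"))
  m <- resolve_mask(r, mask)
  if (!any(m)) abort("all pixels are nodata or masked out")
  bright <- Reduce(`+`, r$bands) / n_bands(r)
  bright[is.na(bright)] <- min(bright, na.rm = TRUE)
  surf <- gaussian_smooth(bright, params$gaussian_sigma_px)
  if (params$input == "gradient") {
    gx <- cbind(surf[, 2] - surf[, 1],
                (surf[, -(1:2), drop = FALSE] -
                   surf[, 1:(ncol(surf) - 2), drop = FALSE]) / 2,
                surf[, ncol(surf)] - surf[, ncol(surf) - 1])
    gy <- rbind(surf[2, ] - surf[1, ],
                (surf[-(1:2), , drop = FALSE] -
                   surf[1:(nrow(surf) - 2), , drop = FALSE]) / 2,
                surf[nrow(surf), ] - surf[nrow(surf) - 1, ])
    surf <- -sqrt(gx^2 + gy^2)    # flood low-gradient interiors
  }
  rng <- range(surf[m])
  if (diff(rng) < 1e-12) {
    warning("constant image: returning a single segment")
    lab <- matrix(0L, nrow(m), ncol(m)); lab[m] <- 1L
  } else {
    x <- (surf - rng[1]) / diff(rng)
    x[!m] <- 0
    # tiny floor keeps foreground pixels above the background level
    x[m] <- pmax(x[m], 1e-6)
    ws <- EBImage::watershed(EBImage::as.Image(x),
                             tolerance = params$h_frac, ext = 1L)
    lab <- matrix(as.integer(EBImage::imageData(ws)), nrow(m), ncol(m))
    lab[!m] <- 0L
    # relabel contiguously in scan order
    ids <- unique(lab[lab > 0L])
    lab[lab > 0L] <- match(lab[lab > 0L], ids)
  }
  canopy_raster(lab, r$cell_size_m, r$origin, role = "segmentmap",
                band_names = "label")
}

#' Per-crown geometry from a segment map
#'
#' For every segment, the two crown extents are measured as the range of
#' pixel-centre projections on the principal axes of the segment's pixel
#' coordinates, plus half a cell on each side; crown width is the mean
#' of the two extents — the airborne analogue of averaging two
#' perpendicular field-measured crown diameters.  Segments with equal
#' principal eigenvalues use the map axes (deterministic tie-break).
#'
#' @param segmap a segment-map [canopy_raster].
#' @param min_segment_px segments smaller than this are dropped.
#' @return data frame: `segment_id`, centroid `x`/`y` (m), `n_px`,
#'   `extent_major_m`, `extent_minor_m`, `crown_width_m`.
#' @export
crown_metrics <- function(segmap, min_segment_px = 10L) {
  stopifnot(inherits(segmap, "canopy_raster"))
  lab <- segmap$bands[[1]]
  if (!any(lab > 0)) abort("segment map has no segments")
  cell <- segmap$cell_size_m
  ctr <- pixel_centers(segmap)
  idx <- which(lab > 0)
  rc <- arrayInd(idx, dim(lab))
  px <- data.frame(label = lab[idx], x = ctr$x[rc[, 2]],
                   y = ctr$y[rc[, 1]])
  out <- lapply(split(px[c("x", "y")], px$label), function(p) {
    n <- nrow(p)
    if (n < min_segment_px) return(NULL)
    xy <- cbind(p$x, p$y)
    cen <- colMeans(xy)
    if (n == 1L) {
      e <- c(cell, cell)
    } else {
      cv <- cov(xy) * (n - 1) / n
      ev <- eigen(cv, symmetric = TRUE)
      axes <- if (abs(ev$values[1] - ev$values[2]) <
                  1e-9 * (abs(ev$values[1]) + 1e-12))
        diag(2) else ev$vectors
      pr <- sweep(xy, 2, cen) %*% axes
      e <- apply(pr, 2, function(v) diff(range(v))) + cell
      e <- sort(e, decreasing = TRUE)
    }
    data.frame(x = cen[1], y = cen[2], n_px = n,
               extent_major_m = e[1], extent_minor_m = e[2])
  })
  keep <- !vapply(out, is.null, logical(1))
  if (!any(keep)) abort("no segment reaches min_segment_px = %d",
                        min_segment_px)
  res <- do.call(rbind, out[keep])
  res <- cbind(segment_id = as.integer(names(out)[keep]), res)
  res$crown_width_m <- (res$extent_major_m + res$extent_minor_m) / 2
  rownames(res) <- NULL
  res
}

#' Tree heights from a CHM, per segment
#'
#' The height assigned to each crown is the maximum CHM value inside its
#' segment — the "brightest pixel" of the canopy in the height model.
#'
#' @param crowns data frame from [crown_metrics()].
#' @param segmap the segment map the crowns came from.
#' @param chm a CHM [canopy_raster] aligned with `segmap`.
#' @return `crowns` with a `tree_height_m` column (`NA`, with a warning,
#'   for segments lying entirely on CHM nodata).
#' @export
crown_heights <- function(crowns, segmap, chm) {
  stopifnot(inherits(segmap, "canopy_raster"),
            inherits(chm, "canopy_raster"))
  if (!same_geometry(segmap, chm))
    abort("segment map (%s) and CHM (%s) are misaligned",
          geometry_string(segmap), geometry_string(chm))
  lab <- segmap$bands[[1]]; h <- chm$bands[[1]]
  idx <- which(lab > 0 & !is.na(h))
  mx <- tapply(h[idx], lab[idx], max)
  crowns$tree_height_m <- unname(mx[as.character(crowns$segment_id)])
  if (anyNA(crowns$tree_height_m))
    warning(sprintf("%d segment(s) lie entirely on CHM nodata",
                    sum(is.na(crowns$tree_height_m))))
  crowns
}

#' Match delineated crowns to field stems
#'
#' Each field stem is matched to the segment containing its `(x, y)`
#' location; stems outside every segment fall back to the nearest crown
#' centroid within `radius_m`.  Matching is one-to-one, resolved
#' greedily by ascending distance, and unmatched stems are flagged.
#'
#' @param crowns data frame from [crown_metrics()].
#' @param field field table (`tree_id`, `x_m`, `y_m`, ...).
#' @param segmap optional segment map for point-in-segment containment.
#' @param radius_m fallback matching radius (m).
#' @return `field` with columns `segment_id` (NA when unmatched),
#'   `match_dist_m` and the matched crown's `crown_width_m` /
#'   `tree_height_m` where available.
#' @export
match_to_field <- function(crowns, field, segmap = NULL, radius_m = 5) {
  stopifnot(is.data.frame(crowns), is.data.frame(field))
  nf <- nrow(field)
  cand <- vector("list", nf)
  contain <- rep(NA_integer_, nf)
  if (!is.null(segmap)) {
    rc <- cell_at(segmap, field$x_m, field$y_m)
    ok <- !is.na(rc$row)
    contain[ok] <- segmap$bands[[1]][cbind(rc$row[ok], rc$col[ok])]
    contain[!is.na(contain) & contain == 0L] <- NA_integer_
  }
  # candidate (stem, segment, distance) pairs
  pairs <- NULL
  for (i in seq_len(nf)) {
    if (!is.na(contain[i]) &&
        contain[i] %in% crowns$segment_id) {
      pairs <- rbind(pairs, data.frame(stem = i, seg = contain[i],
                                       dist = 0))
    } else {
      d <- sqrt((crowns$x - field$x_m[i])^2 +
                  (crowns$y - field$y_m[i])^2)
      near <- which(d <= radius_m)
      if (length(near))
        pairs <- rbind(pairs, data.frame(
          stem = i, seg = crowns$segment_id[near], dist = d[near]))
    }
  }
  field$segment_id <- NA_integer_
  field$match_dist_m <- NA_real_
  if (!is.null(pairs)) {
    pairs <- pairs[order(pairs$dist, pairs$stem, pairs$seg), ]
    used_seg <- integer(); used_stem <- integer()
    for (k in seq_len(nrow(pairs))) {
      s <- pairs$stem[k]; g <- pairs$seg[k]
      if (s %in% used_stem || g %in% used_seg) next
      field$segment_id[s] <- g
      field$match_dist_m[s] <- pairs$dist[k]
      used_stem <- c(used_stem, s); used_seg <- c(used_seg, g)
    }
  }
  at <- match(field$segment_id, crowns$segment_id)
  field$pred_crown_width_m <- crowns$crown_width_m[at]
  if ("tree_height_m" %in% names(crowns))
    field$pred_tree_height_m <- crowns$tree_height_m[at]
  field$matched <- !is.na(field$segment_id)
  field
}
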