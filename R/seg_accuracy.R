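#' Rasterize reference polygons onto a segment-map grid
#'
#' Pixel centres falling inside each polygon (even-odd rule, via
#' [mgcv::in.out()]) define its pixel set; all area arithmetic in the
#' accuracy metrics then happens on this common grid, so a reference
#' identical to a segment scores exactly zero error.
#'
#' @param pset a [polygon_set].
#' @param segmap a [canopy_raster] providing the grid.
#' @return named list of pixel index vectors (linear indices), one per
#'   polygon id.
#' @keywords internal
rasterize_polygons <- function(pset, segmap) {
  ctr <- pixel_centers(segmap)
  d <- dim(segmap)
  out <- lapply(pset$polygons, function(p) {
    bb <- apply(p$coords, 2, range)
    cols <- which(ctr$x >= bb[1, 1] - segmap$cell_size_m &
                    ctr$x <= bb[2, 1] + segmap$cell_size_m)
    rows <- which(ctr$y >= bb[1, 2] - segmap$cell_size_m &
                    ctr$y <= bb[2, 2] + segmap$cell_size_m)
    if (!length(cols) || !length(rows)) return(integer())
    g <- expand.grid(r = rows, c = cols)
    ring <- rbind(p$coords, p$coords[1, , drop = FALSE])
    inside <- mgcv::in.out(ring, cbind(ctr$x[g$c], ctr$y[g$r]))
    ((g$c[inside] - 1L) * d[1]) + g$r[inside]
  })
  names(out) <- vapply(pset$polygons, function(p) as.character(p$id), "")
  out
}

#' Pair reference crowns with their best-overlapping segments
#'
#' Each reference polygon is paired with the segment of maximal
#' intersection area on the segment-map grid; references intersecting no
#' segment are flagged unmatched.
#'
#' @param reference a [polygon_set] of reference crowns.
#' @param segmap a segment-map [canopy_raster].
#' @return data frame: `ref_id`, `segment_id` (NA if unmatched),
#'   `n_ref_px`, `n_seg_px`, `n_intersection_px`.
#' @export
match_reference <- function(reference, segmap) {
  stopifnot(inherits(reference, "polygon_set"),
            inherits(segmap, "canopy_raster"))
  if (!length(reference)) abort("empty reference polygon set")
  lab <- segmap$bands[[1]]
  seg_sizes <- table(lab[lab > 0])
  ref_px <- rasterize_polygons(reference, segmap)
  rows <- lapply(names(ref_px), function(id) {
    px <- ref_px[[id]]
    labs <- lab[px]
    labs <- labs[labs > 0]
    if (!length(labs))
      return(data.frame(ref_id = id, segment_id = NA_integer_,
                        n_ref_px = length(px), n_seg_px = NA_integer_,
                        n_intersection_px = 0L))
    tab <- table(labs)
    best <- names(tab)[which.max(tab)]   # ties: lowest label (table order)
    data.frame(ref_id = id, segment_id = as.integer(best),
               n_ref_px = length(px),
               n_seg_px = as.integer(seg_sizes[best]),
               n_intersection_px = as.integer(max(tab)))
  })
  do.call(rbind, rows)
}

#' Over- and undersegmentation of a matched pair
#'
#' Area-ratio definitions: `over = 1 - area(ref & seg) / area(ref)`
#' (part of the ground crown missed by its segment, i.e. the crown is
#' split across segments) and `under = 1 - area(ref & seg) / area(seg)`
#' (part of the segment spilling beyond the crown, i.e. the segment
#' spans several crowns).  Both are clipped to `[0, 1]`.
#'
#' @param area_ref,area_seg,area_int areas (any common unit) of the
#'   reference, the segment, and their intersection.
#' @return named numeric `c(over, under)`.
#' @export
over_under <- function(area_ref, area_seg, area_int) {
  if (area_ref <= 0 || area_seg <= 0)
    abort("zero-area geometry in over/undersegmentation")
  c(over = min(max(1 - area_int / area_ref, 0), 1),
    under = min(max(1 - area_int / area_seg, 0), 1))
}

#' Closeness index D
#'
#' `D = sqrt(over^2 + under^2)`: Euclidean distance of a matched
#' reference/segment pair from perfect overlap.  Zero means a perfect
#' match; the maximum is `sqrt(2)`.
#'
#' @param over,under over- and undersegmentation rates in `[0, 1]`.
#' @return D (non-negative scalar, vectorised over inputs).
#' @export
closeness_index <- function(over, under) {
  if (any(over < -1e-12) || any(over > 1 + 1e-12) ||
      any(under < -1e-12) || any(under > 1 + 1e-12))
    abort("over/under must lie in [0, 1]")
  sqrt(over^2 + under^2)
}

#' Aggregate closeness over a set of matched references
#'
#' @param records data frame with a `D` column (see
#'   [evaluate_segmentation()]); unmatched references (`NA` D) are
#'   excluded.
#' @return list with `mean_D` and `accuracy_pct = 100 * (1 - mean_D)`.
#' @export
aggregate_D <- function(records) {
  d <- records$D[!is.na(records$D)]
  if (!length(d)) abort("no matched references to aggregate")
  list(mean_D = mean(d), accuracy_pct = 100 * (1 - mean(d)))
}

#' Score a segmentation against reference crowns
#'
#' Full accuracy battery: match each reference polygon to its
#' best-overlapping segment, compute over/undersegmentation and the
#' closeness index D per reference, and aggregate.
#'
#' @param reference a [polygon_set] of reference crowns.
#' @param segmap a segment-map [canopy_raster].
#' @return data frame of per-reference records (`ref_id`, `segment_id`,
#'   `over`, `under`, `D`) with the [aggregate_D()] summary attached as
#'   attribute `"aggregate"`.
#' @export
evaluate_segmentation <- function(reference, segmap) {
  m <- match_reference(reference, segmap)
  m$over <- NA_real_; m$under <- NA_real_; m$D <- NA_real_
  ok <- !is.na(m$segment_id)
  for (i in which(ok)) {
    ou <- over_under(m$n_ref_px[i], m$n_seg_px[i],
                     m$n_intersection_px[i])
    m$over[i] <- ou["over"]; m$under[i] <- ou["under"]
    m$D[i] <- closeness_index(ou["over"], ou["under"])
  }
  attr(m, "aggregate") <- aggregate_D(m)
  m
}
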