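test_that("region merging honours the scale threshold on flat and split images", {
  uni <- canopy_raster(matrix(5, 12, 12), 1)
  seg <- multiresolution_segment(uni, seg_params(scale = 1, w_color = 1))
  expect_equal(max(seg$bands[[1]]), 1L)
  # two constant halves: a small scale keeps them apart, with the
  # boundary exactly on the true edge
  m <- cbind(matrix(0, 10, 5), matrix(255, 10, 5))
  seg2 <- multiresolution_segment(canopy_raster(m, 1),
                                  seg_params(scale = 5))
  lab <- seg2$bands[[1]]
  expect_equal(max(lab), 2L)
  expect_equal(length(unique(as.vector(lab[, 1:5]))), 1L)
  expect_equal(length(unique(as.vector(lab[, 6:10]))), 1L)
  expect_false(lab[1, 5] == lab[1, 6])
  # a huge scale merges everything
  seg3 <- multiresolution_segment(canopy_raster(m, 1),
                                  seg_params(scale = 1e6))
  expect_equal(max(seg3$bands[[1]]), 1L)
})

test_that("every pixel gets exactly one label and labels are contiguous", {
  sc <- cached_scene("small6", small_scene_params(seed = 7))
  seg <- multiresolution_segment(sc$imagery, seg_params(scale = 40))
  lab <- seg$bands[[1]]
  expect_equal(length(lab), prod(dim(sc$imagery)))
  expect_setequal(unique(as.vector(lab)), seq_len(max(lab)))
  expect_equal(sum(table(lab)), length(lab))
})

test_that("raising the scale never increases the segment count", {
  set.seed(11)
  base <- canopyseg:::gaussian_smooth(
    matrix(rnorm(900, 100, 30), 30, 30), 2)
  r <- canopy_raster(base, 1)
  counts <- vapply(c(2, 5, 10, 20, 40), function(s)
    max(multiresolution_segment(r, seg_params(scale = s))$bands[[1]]),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("segmentation is deterministic and rejects all-nodata input", {
  sc <- cached_scene("small6", small_scene_params(seed = 7))
  a <- multiresolution_segment(sc$imagery, seg_params(scale = 40))
  b <- multiresolution_segment(sc$imagery, seg_params(scale = 40))
  expect_identical(a$bands, b$bands)
  allna <- canopy_raster(matrix(NA_real_, 4, 4), 1)
  expect_error(multiresolution_segment(allna, seg_params(scale = 5)),
               "nodata")
})

test_that("watershed separates blobs and labels their centres correctly", {
  n <- 60
  g <- expand.grid(r = 1:n, c = 1:n)
  blob <- function(r0, c0) matrix(exp(-((g$r - r0)^2 + (g$c - c0)^2) /
                                        (2 * 5^2)), n, n)
  one <- canopy_raster(200 * blob(30, 30) + 5, 1)
  m1 <- one$bands[[1]] > 30
  s1 <- watershed_segment(one, seg_params(), mask = m1)
  expect_equal(max(s1$bands[[1]]), 1L)
  two <- canopy_raster(200 * blob(30, 15) + 190 * blob(30, 45) + 5, 1)
  m2 <- two$bands[[1]] > 30
  s2 <- watershed_segment(two, seg_params(), mask = m2)
  lab <- s2$bands[[1]]
  expect_equal(max(lab), 2L)
  for (ctr in list(c(30, 15), c(30, 45))) {
    l <- lab[ctr[1], ctr[2]]
    idx <- which(lab == l, arr.ind = TRUE)
    expect_lt(sqrt(sum((colMeans(idx) - ctr)^2)), 2)
  }
})

test_that("a constant image yields one segment with a warning", {
  flat <- canopy_raster(matrix(3, 8, 8), 1)
  expect_warning(s <- watershed_segment(flat, seg_params()), "constant")
  expect_equal(max(s$bands[[1]]), 1L)
})

test_that("crown metrics follow the principal-axis extent definition", {
  # single-pixel segment: width = one cell
  lab <- matrix(0L, 5, 5); lab[3, 3] <- 1L
  sm <- canopy_raster(lab, 0.5, role = "segmentmap")
  cm <- crown_metrics(sm, min_segment_px = 1)
  expect_equal(cm$crown_width_m, 0.5)
  # 10 x 10 square, 1 m cells: both extents 10 (axis-aligned tie-break)
  lab2 <- matrix(0L, 14, 14); lab2[3:12, 3:12] <- 1L
  cm2 <- crown_metrics(canopy_raster(lab2, 1, role = "segmentmap"))
  expect_equal(cm2$extent_major_m, 10)
  expect_equal(cm2$extent_minor_m, 10)
  expect_equal(cm2$crown_width_m, 10)
  # rasterized disc of radius ~10 px: width 20 m within 5%
  g <- expand.grid(r = 1:27, c = 1:27)
  lab3 <- matrix(as.integer((g$r - 13.5)^2 + (g$c - 13.5)^2 <= 9.6^2),
                 27, 27)
  cm3 <- crown_metrics(canopy_raster(lab3, 1, role = "segmentmap"))
  expect_lt(abs(cm3$crown_width_m - 20) / 20, 0.05)
  # small segments are dropped
  lab4 <- lab2; lab4[1, 1] <- 2L
  cm4 <- crown_metrics(canopy_raster(lab4, 1, role = "segmentmap"),
                       min_segment_px = 10)
  expect_equal(cm4$segment_id, 1L)
})

test_that("crown heights take the per-segment CHM maximum", {
  lab <- matrix(0L, 6, 6); lab[2:4, 2:4] <- 1L; lab[5:6, 5:6] <- 2L
  sm <- canopy_raster(lab, 1, role = "segmentmap")
  h <- matrix(20, 6, 6); h[3, 3] <- 31.5; h[5, 5] <- NA; h[6, 6] <- NA
  h[5, 6] <- NA; h[6, 5] <- NA
  chm <- canopy_raster(h, 1, role = "chm")
  cm <- crown_metrics(sm, min_segment_px = 1)
  expect_warning(out <- crown_heights(cm, sm, chm), "nodata")
  expect_equal(out$tree_height_m[out$segment_id == 1L], 31.5)
  expect_true(is.na(out$tree_height_m[out$segment_id == 2L]))
  badchm <- canopy_raster(h, 1, origin = c(9, 9))
  expect_error(crown_heights(cm, sm, badchm), "misaligned")
})

test_that("field stems match containing segments, then nearest centroids", {
  lab <- matrix(0L, 20, 20)
  lab[3:8, 3:8] <- 1L       # centred near (5.5, 14.5) in map coords
  lab[12:17, 12:17] <- 2L
  sm <- canopy_raster(lab, 1, role = "segmentmap", origin = c(0, 20))
  cm <- crown_metrics(sm, min_segment_px = 1)
  field <- data.frame(tree_id = 1:3,
                      x_m = c(5.5, 18.0, 14.5),
                      y_m = c(14.5, 18.5, 5.5))
  m <- match_to_field(cm, field, segmap = sm, radius_m = 6)
  expect_equal(m$segment_id[1], 1L)       # inside segment 1
  expect_equal(m$segment_id[3], 2L)       # inside segment 2
  expect_true(is.na(m$segment_id[2]))     # too far from any centroid
  # greedy one-to-one: of two stems nearest the same segment, the
  # closer one wins and the other stays unmatched
  f2 <- data.frame(tree_id = 1:2, x_m = c(6.0, 9.0), y_m = c(15, 15))
  m2 <- match_to_field(cm[cm$segment_id == 1L, ], f2, segmap = sm,
                       radius_m = 8)
  expect_equal(m2$segment_id[1], 1L)
  expect_true(is.na(m2$segment_id[2]))
})
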