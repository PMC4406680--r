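test_that("an empty scene has background imagery, ground-only returns", {
  sc <- generate_scene(small_scene_params(n_trees = 0))
  expect_equal(nrow(sc$truth$crowns), 0L)
  expect_true(all(sc$cloud$return_number == 1L))
  # all returns within noise of the terrain
  zt <- canopyseg:::terrain_z(sc$truth$terrain, sc$cloud$x, sc$cloud$y)
  expect_lt(max(abs(sc$cloud$z - zt)), 0.25)
  # imagery stays near the background spectrum
  expect_lt(abs(mean(sc$imagery$bands[[1]]) - 150), 2)
})

test_that("identical parameters and seed give bit-identical scenes", {
  a <- generate_scene(small_scene_params(seed = 31))
  b <- generate_scene(small_scene_params(seed = 31))
  expect_identical(a$imagery$bands, b$imagery$bands)
  expect_identical(a$cloud, b$cloud)
  expect_identical(a$truth$crowns, b$truth$crowns)
  c <- generate_scene(small_scene_params(seed = 32))
  expect_false(identical(a$truth$crowns, c$truth$crowns))
})

test_that("disjoint placement yields non-overlapping crowns and bounded canopy returns", {
  sc <- cached_scene("std25", scene_params(n_trees = 25, seed = 42))
  crowns <- sc$truth$crowns
  expect_equal(nrow(crowns), 25L)
  refs <- truth_to_reference_polygons(sc$truth)
  # brute-force: no vertex of any polygon falls inside another polygon
  for (i in seq_len(25)) {
    for (j in seq_len(25)) {
      if (i == j) next
      ci <- refs$polygons[[i]]$coords
      cj <- refs$polygons[[j]]$coords
      hits <- sum(vapply(seq_len(nrow(ci)), function(k)
        oracle_in_poly(ci[k, 1], ci[k, 2], cj), logical(1)))
      expect_equal(hits, 0L)
    }
  }
  # canopy return heights stay below tree height (plus return noise)
  canopy <- sc$cloud[sc$cloud$return_number == 1L, ]
  for (i in sample(25, 6)) {
    p <- refs$polygons[[i]]
    inside <- vapply(seq_len(nrow(canopy)), function(k)
      oracle_in_poly(canopy$x[k], canopy$y[k], p$coords), logical(1))
    zt <- canopyseg:::terrain_z(sc$truth$terrain, crowns$x[i],
                                crowns$y[i])
    above <- canopy$z[inside] - zt
    above <- above[above > 2]         # canopy (not ground) returns
    expect_lt(max(above), crowns$height_m[i] + 0.6)
  }
})

test_that("return density matches the requested point density within 10%", {
  sc <- cached_scene("std25", scene_params(n_trees = 25, seed = 42))
  dens <- nrow(sc$cloud) / 200^2
  expect_lt(abs(dens - 12) / 12, 0.10)
})

test_that("placement fails loudly when spacing cannot be honoured", {
  expect_error(
    generate_scene(scene_params(extent_m = 60, n_trees = 40, seed = 1)),
    "minimum stem spacing")
})

test_that("reference polygons have unique ids and ellipse-accurate areas", {
  sc <- cached_scene("std25", scene_params(n_trees = 25, seed = 42))
  refs <- truth_to_reference_polygons(sc$truth)
  expect_equal(length(refs), 25L)
  ids <- vapply(refs$polygons, function(p) p$id, numeric(1))
  expect_equal(sort(ids), 1:25)
  for (i in c(1, 10, 25)) {
    cr <- sc$truth$crowns[i, ]
    a_true <- pi * cr$axis_major_m * cr$axis_minor_m / 4
    expect_lt(abs(polygon_area(refs$polygons[[i]]$coords) - a_true) /
                a_true, 0.02)
  }
  # circular crown of radius 5 -> area ~ pi * 25
  tr <- structure(list(
    crowns = data.frame(tree_id = 1L, species = "A", x = 0, y = 0,
                        axis_major_m = 10, axis_minor_m = 10, rot = 0,
                        height_m = 30, crown_width_m = 10),
    terrain = c(base = 0, slope = 0, undulation = 0), extent_m = 50,
    cell_size_m = 0.5), class = "scene_truth")
  a <- polygon_area(truth_to_reference_polygons(tr)$polygons[[1]]$coords)
  expect_lt(abs(a - pi * 25) / (pi * 25), 0.02)
  # empty truth -> empty set
  tr0 <- tr; tr0$crowns <- tr$crowns[0, ]
  expect_equal(length(truth_to_reference_polygons(tr0)), 0L)
})

test_that("crown width equals the mean of the two ellipse axes", {
  sc <- cached_scene("std25", scene_params(n_trees = 25, seed = 42))
  cr <- sc$truth$crowns
  expect_equal(cr$crown_width_m, (cr$axis_major_m + cr$axis_minor_m) / 2)
  st <- scene_params()$species_table
  at <- match(cr$species, st$species)
  expect_true(all(cr$height_m >= st$height_min[at] &
                    cr$height_m <= st$height_max[at]))
})

test_that("field tables reproduce truth at zero error and calibrated noise", {
  sc <- cached_scene("std25", scene_params(n_trees = 25, seed = 42))
  ft <- truth_field_table(sc$truth, 0, 0, seed = 3)
  expect_equal(ft$height_m, sc$truth$crowns$height_m)
  expect_equal(ft$crown_width_m, sc$truth$crowns$crown_width_m)
  n1 <- truth_field_table(sc$truth, 1.5, 0.8, seed = 9)
  n2 <- truth_field_table(sc$truth, 1.5, 0.8, seed = 9)
  expect_identical(n1, n2)
  expect_false(identical(n1$height_m, ft$height_m))
  expect_error(truth_field_table(sc$truth, -1, 0), ">= 0")
  # calibration: with 200 crowns the sample sd of (field - truth)
  # recovers the requested error sd
  big <- structure(list(
    crowns = data.frame(tree_id = 1:200, species = "A",
                        x = runif(200, 0, 1000), y = runif(200, 0, 1000),
                        axis_major_m = 12, axis_minor_m = 10, rot = 0,
                        height_m = runif(200, 25, 40),
                        crown_width_m = runif(200, 8, 20)),
    terrain = c(base = 0, slope = 0, undulation = 0), extent_m = 1000,
    cell_size_m = 0.5), class = "scene_truth")
  fb <- truth_field_table(big, height_error_sd = 1.0, seed = 5)
  err_sd <- sd(fb$height_m - big$crowns$height_m)
  expect_gt(err_sd, 0.8)
  expect_lt(err_sd, 1.2)
})

test_that("crown pixel samples carry the right labels and features", {
  sc <- cached_scene("std25", scene_params(n_trees = 25, seed = 42))
  s <- sample_crown_pixels(sc$imagery, sc$truth, per_crown = 20, seed = 1)
  expect_true(all(c("red", "green", "blue", "class", "tree_id") %in%
                    names(s)))
  expect_lte(max(table(s$tree_id)), 20)
  expect_identical(
    s$class, sc$truth$crowns$species[match(s$tree_id,
                                           sc$truth$crowns$tree_id)])
  s2 <- sample_crown_pixels(sc$imagery, sc$truth, per_crown = 20, seed = 1)
  expect_identical(s, s2)
})
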