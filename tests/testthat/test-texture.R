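test_that("single-window GLCMs follow their closed forms", {
  # constant window: all mass at one diagonal entry
  g <- glcm(matrix(5, 5, 5), texture_params(levels = 8), rng = c(0, 10))
  expect_equal(sum(g), 1)
  expect_equal(g[5, 5], 1)   # 5 on [0,10] at 8 levels -> level 4 (1-based 5)
  # two-level vertical stripes, horizontal offset: all mass off-diagonal
  stripes <- matrix(rep(c(0, 1), 3), 6, 6, byrow = TRUE)
  g2 <- glcm(stripes, texture_params(levels = 2,
                                     offsets = matrix(c(0L, 1L), 1)),
             rng = c(0, 1))
  expect_equal(g2[1, 1] + g2[2, 2], 0)
  expect_equal(g2[1, 2] + g2[2, 1], 1)
  expect_error(glcm(matrix(1, 1, 1), texture_params()), "offset reach")
})

test_that("GLCMs match a brute-force pair-enumeration oracle", {
  set.seed(13)
  prm <- texture_params(levels = 6)
  for (i in 1:100) {
    w <- matrix(runif(25, 0, 100), 5, 5)
    sym <- i %% 2 == 0
    p <- texture_params(levels = 6, symmetric = sym)
    got <- glcm(w, p, rng = c(0, 100))
    expect_equal(got, oracle_glcm(w, 6, p$offsets, sym, c(0, 100)))
    expect_equal(sum(got), 1)
    expect_true(all(got >= 0))
  }
})

test_that("texture bands obey constant-image and checkerboard closed forms", {
  flat <- canopy_raster(matrix(7, 10, 10), 1)
  tp <- texture_params(window = 5, levels = 8,
                       features = c("mean", "variance", "entropy1",
                                    "contrast", "ASM", "entropy2"))
  tb <- texture_bands(flat, tp)
  expect_true(all(tb$bands$band1_contrast == 0))
  expect_true(all(tb$bands$band1_ASM == 1))
  expect_true(all(tb$bands$band1_entropy2 == 0))
  expect_true(all(tb$bands$band1_variance == 0))
  expect_true(all(tb$bands$band1_mean == 7))
  # checkerboard, 2 levels, symmetric, offset (0,1): two off-diagonal
  # entries of 0.5 -> co-occurrence entropy of exactly 1 bit
  cb <- matrix(0, 12, 12)
  cb[(row(cb) + col(cb)) %% 2 == 0] <- 1
  tcb <- texture_bands(canopy_raster(cb, 1),
                       texture_params(window = 5, levels = 2,
                                      offsets = matrix(c(0L, 1L), 1),
                                      features = "entropy2"))
  # away from the mirrored edge every window has two off-diagonal
  # entries of 0.5 -> exactly 1 bit
  expect_true(all(abs(tcb$bands$band1_entropy2[, 3:10] - 1) < 1e-12))
})

test_that("windowed features agree with the single-window implementation", {
  set.seed(14)
  m <- matrix(runif(400, 0, 255), 20, 20)
  r <- canopy_raster(m, 1)
  tp <- texture_params(window = 5, levels = 8,
                       features = c("mean", "variance", "entropy1",
                                    "contrast", "ASM", "entropy2",
                                    "homogeneity", "dissimilarity"))
  tb <- texture_bands(r, tp)
  rng <- range(m)
  for (px in list(c(8, 9), c(3, 14), c(17, 6))) {
    win <- m[px[1] + (-2:2), px[2] + (-2:2)]
    g <- glcm(win, tp, rng = rng)
    d <- abs(row(g) - col(g))
    expect_equal(tb$bands$band1_mean[px[1], px[2]], mean(win))
    expect_equal(tb$bands$band1_variance[px[1], px[2]],
                 mean((win - mean(win))^2))
    expect_equal(tb$bands$band1_contrast[px[1], px[2]],
                 sum(g * d^2))
    expect_equal(tb$bands$band1_ASM[px[1], px[2]], sum(g^2))
    expect_equal(tb$bands$band1_entropy2[px[1], px[2]],
                 -sum(g[g > 0] * log2(g[g > 0])))
    expect_equal(tb$bands$band1_homogeneity[px[1], px[2]],
                 sum(g / (1 + d^2)))
    expect_equal(tb$bands$band1_dissimilarity[px[1], px[2]],
                 sum(g * d))
    q <- canopyseg:::quantize_band(win, 8, rng)
    h <- tabulate(q + 1L, 8)
    p <- h[h > 0] / sum(h)
    expect_equal(tb$bands$band1_entropy1[px[1], px[2]],
                 -sum(p * log2(p)))
  }
})

test_that("feature value bounds hold on random imagery", {
  set.seed(15)
  r <- canopy_raster(matrix(rnorm(225, 100, 25), 15, 15), 1)
  tp <- texture_params(window = 5, levels = 16,
                       features = c("ASM", "entropy2", "contrast"))
  tb <- texture_bands(r, tp)
  expect_true(all(tb$bands$band1_ASM > 0 & tb$bands$band1_ASM <= 1))
  expect_true(all(tb$bands$band1_entropy2 >= 0 &
                    tb$bands$band1_entropy2 <= 2 * log2(16)))
  expect_true(all(tb$bands$band1_contrast >= 0))
})

test_that("gain ratio rewards informative features and is scale-invariant", {
  d <- data.frame(class = rep(c("a", "b"), each = 20),
                  perfect = rep(c(0, 1), each = 20),
                  constant = 5,
                  noise = NA)
  set.seed(16)
  d$noise <- rnorm(40)
  rk <- gain_ratio_rank(d, bins = 2)
  expect_equal(rk$feature[1], "perfect")
  expect_equal(rk$gain_ratio[1], 1)
  expect_equal(rk$gain_ratio[rk$feature == "constant"], 0)
  # invariance under monotone rescaling (equal-frequency bins)
  d2 <- d
  d2$noise <- exp(3 * d$noise + 7)
  rk2 <- gain_ratio_rank(d2, bins = 2)
  expect_equal(rk$gain_ratio, rk2$gain_ratio)
  expect_true(all(rk$gain_ratio >= 0 & rk$gain_ratio <= 1))
  expect_error(gain_ratio_rank(data.frame(class = "a", x = 1:5)),
               "2 classes")
})

test_that("gain ratio reproduces hand-computed entropies on a toy table", {
  # 8 rows, 2 classes; f1 splits 3/1 vs 1/3 across its two halves
  toy <- data.frame(class = c("a", "a", "a", "b", "a", "b", "b", "b"),
                    f1 = c(1, 2, 3, 4, 5, 6, 7, 8),
                    f2 = c(1, 1, 2, 2, 1, 1, 2, 2))
  rk <- gain_ratio_rank(toy, bins = 2)
  # hand computation for f1 with an equal-frequency 2-bin split at 4.5:
  # H(class) = 1; H(class|bin) = 0.8113; H(bin) = 1
  h <- function(p) -sum(p[p > 0] * log2(p[p > 0]))
  ig_f1 <- 1 - (0.5 * h(c(3, 1) / 4) + 0.5 * h(c(1, 3) / 4))
  expect_equal(rk$gain_ratio[rk$feature == "f1"], ig_f1)
  # f2: bins {1,1,1,1} / {2,2,2,2}, classes 3a1b / 1a3b -> same IG
  expect_equal(rk$gain_ratio[rk$feature == "f2"], ig_f1)
})

test_that("entropy of the red band tops the ranking for a texture-only pair", {
  p <- scene_params(n_trees = 12, extent_m = 120, seed = 5,
                    species_table = texture_pair_species())
  sc <- generate_scene(p)
  tp <- texture_params(features = c("mean", "variance", "entropy1",
                                    "contrast", "ASM", "entropy2",
                                    "homogeneity", "dissimilarity"))
  tex <- texture_bands(sc$imagery, tp)
  samp <- sample_crown_pixels(sc$imagery, sc$truth, per_crown = 60,
                              seed = 2, extra = list(tex))
  samp$tree_id <- NULL
  rk <- gain_ratio_rank(samp, bins = 10)
  expect_true(rk$feature[1] %in% c("red_entropy1", "red_entropy2"))
})
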