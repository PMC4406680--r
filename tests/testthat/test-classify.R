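test_that("stratified splits are disjoint, exhaustive and reproducible", {
  d <- data.frame(f = rnorm(20), class = rep(c("a", "b"), each = 10))
  sp <- split_samples(d, 0.7, seed = 2)
  expect_equal(nrow(sp$train), 14)
  expect_equal(nrow(sp$test), 6)
  expect_equal(table(sp$train$class), table(sp$test$class) * 7 / 3,
               ignore_attr = TRUE)
  all_rows <- rbind(sp$train, sp$test)
  expect_setequal(rownames(all_rows), rownames(d))
  sp2 <- split_samples(d, 0.7, seed = 2)
  expect_identical(sp, sp2)
  sp3 <- split_samples(d, 0.7, seed = 3)
  expect_false(identical(sp$train, sp3$train))
  expect_error(split_samples(data.frame(f = 1:3,
                                        class = c("a", "a", "b"))),
               "'b' has fewer than 2")
})

test_that("the ML discriminant places the 1-D two-class boundary at 2", {
  model <- structure(list(
    classes = c("lo", "hi"),
    models = list(lo = list(mu = 0, sigma = matrix(1), inv = matrix(1),
                            logdet = 0),
                  hi = list(mu = 4, sigma = matrix(1), inv = matrix(1),
                            logdet = 0)),
    priors = c(lo = 0.5, hi = 0.5), features = NULL),
    class = "ml_model")
  expect_equal(classify_ml(matrix(c(1.9, 1.999, 2.001, 2.1)), model),
               c("lo", "lo", "hi", "hi"))
  # a pixel at a class mean with shared covariance takes that class
  expect_equal(classify_ml(matrix(c(0, 4)), model), c("lo", "hi"))
  # probability threshold leaves a far outlier unclassified
  expect_true(is.na(classify_ml(matrix(100), model,
                                threshold = 0.999)))
  expect_error(classify_ml(matrix(1, 1, 2), model), "dimension mismatch")
})

test_that("ML decisions match a brute-force Gaussian-discriminant oracle", {
  set.seed(17)
  for (i in 1:100) {
    K <- sample(2:4, 1); d <- sample(1:3, 1)
    tr <- do.call(rbind, lapply(seq_len(K), function(k) {
      n <- sample(8:15, 1)
      cbind(matrix(rnorm(n * d, mean = 3 * k), n, d), k)
    }))
    tr <- as.data.frame(tr)
    names(tr) <- c(paste0("f", seq_len(d)), "class")
    tr$class <- paste0("c", tr$class)
    m <- train_ml(tr)
    x <- rnorm(d, mean = 3 * sample(K, 1))
    got <- classify_ml(matrix(x, 1), m)
    want <- m$classes[oracle_ml_decide(
      x, lapply(m$models, `[[`, "mu"),
      lapply(m$models, `[[`, "sigma"), m$priors)]
    expect_identical(got, want)
  }
})

test_that("SAM angles follow the closed forms and scale invariance", {
  lib <- structure(list(classes = c("r1", "r2"),
                        spectra = rbind(c(1, 0, 0), c(0, 1, 0)),
                        features = NULL), class = "sam_library")
  ang <- spectral_angles(rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)), lib)
  expect_equal(unname(ang[1, "r1"]), 0)
  expect_equal(unname(ang[1, "r2"]), pi / 2)
  expect_equal(unname(ang[3, "r1"]), pi / 4)
  # x = 3 * r1 -> angle 0, class r1
  expect_equal(classify_sam(matrix(c(3, 0, 0), 1), lib), "r1")
  # positive per-pixel scaling never changes the decision
  set.seed(18)
  for (i in 1:100) {
    x <- matrix(runif(3, 0.1, 10), 1)
    k <- runif(1, 0.01, 50)
    expect_identical(classify_sam(x, lib), classify_sam(k * x, lib))
    expect_equal(which.min(spectral_angles(x, lib)),
                 oracle_sam_decide(as.vector(x), lib$spectra))
  }
  expect_warning(out <- classify_sam(matrix(0, 1, 3), lib), "zero pixel")
  expect_true(is.na(out))
  expect_true(is.na(classify_sam(matrix(c(1, 1, 0), 1), lib,
                                 max_angle = 0.1)))
})

test_that("ML is sensitive to illumination scaling where SAM is not", {
  set.seed(19)
  tr <- data.frame(f1 = c(rnorm(30, 10), rnorm(30, 20)),
                   f2 = c(rnorm(30, 20), rnorm(30, 10)),
                   class = rep(c("a", "b"), each = 30))
  m <- train_ml(tr)
  s <- train_sam(tr)
  x <- matrix(c(10, 20), 1)
  expect_identical(classify_sam(x, s), classify_sam(5 * x, s))
  expect_false(identical(classify_ml(x, m), classify_ml(5 * x, m)))
})

test_that("accuracy reports reproduce hand-computed confusion statistics", {
  # perfect predictions
  r <- accuracy_report(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(r$overall_accuracy, 1)
  expect_equal(r$kappa, 1)
  expect_true(all(r$producers_accuracy == 100))
  expect_true(all(r$users_accuracy == 100))
  # everything predicted one class over two balanced classes
  r2 <- accuracy_report(rep("a", 10), rep(c("a", "b"), each = 5))
  expect_equal(r2$overall_accuracy, 0.5)
  expect_equal(r2$kappa, 0)
  expect_equal(unname(r2$users_accuracy["b"]), 0)   # never predicted
  # 3x3 toy matrix against direct marginal arithmetic
  ref <- c(rep("a", 6), rep("b", 5), rep("c", 4))
  prd <- c("a", "a", "a", "b", "c", "a", "b", "b", "b", "a", "b", "c",
           "c", "c", "b")
  r3 <- accuracy_report(prd, ref)
  o <- oracle_confusion_stats(prd, ref, c("a", "b", "c"))
  expect_equal(r3$overall_accuracy, o$oa)
  expect_equal(r3$kappa, o$kappa)
  expect_equal(unname(r3$producers_accuracy), unname(o$producers * 100))
  expect_equal(unname(r3$users_accuracy), unname(o$users * 100))
  expect_error(accuracy_report(character(), character()), "empty")
  expect_error(accuracy_report("a", "z", classes = c("a", "b")),
               "missing from the class legend")
})

test_that("kappa never exceeds overall accuracy on random confusions", {
  set.seed(20)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    cls <- letters[seq_len(k)]
    ref <- sample(cls, 60, replace = TRUE)
    prd <- ifelse(runif(60) < 0.6, ref, sample(cls, 60, replace = TRUE))
    r <- accuracy_report(prd, ref, classes = cls)
    expect_lte(r$kappa, r$overall_accuracy + 1e-12)
  }
})

test_that("unclassified predictions are reported both ways", {
  ref <- rep(c("a", "b"), each = 4)
  prd <- c("a", "a", "a", NA, "b", "b", NA, NA)
  r <- accuracy_report(prd, ref)
  expect_equal(r$overall_accuracy, 5 / 8)       # NA counts as wrong
  expect_equal(r$overall_accuracy_classified, 1) # among classified: all ok
  expect_true("unclassified" %in% colnames(r$confusion))
})

test_that("separable species are classified accurately, ML above SAM", {
  p <- scene_params(n_trees = 15, extent_m = 150, seed = 11,
                    species_table = separable_species())
  sc <- generate_scene(p)
  samp <- sample_crown_pixels(sc$imagery, sc$truth, per_crown = 50,
                              seed = 2)
  samp$tree_id <- NULL
  sp <- split_samples(samp, 0.7, seed = 3)
  feats <- c("red", "green", "blue")
  rml <- accuracy_report(
    classify_ml(sp$test[feats], train_ml(sp$train)), sp$test$class)
  rsam <- accuracy_report(
    classify_sam(sp$test[feats], train_sam(sp$train)), sp$test$class)
  expect_gte(rml$overall_accuracy, 0.9)
  expect_gte(rml$overall_accuracy, rsam$overall_accuracy)
})
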