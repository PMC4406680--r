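#' Stratified train/test split
#'
#' Splits a sample table randomly within each class, the usual 70/30
#' protocol for supervised classification of ground-located trees.
#'
#' @param samples data frame with a class column and feature columns.
#' @param train_fraction fraction of each class used for training.
#' @param seed integer seed; the split is reproducible.
#' @param class_col name of the class column.
#' @return list with `train` and `test` data frames (disjoint, union =
#'   `samples`).
#' @export
split_samples <- function(samples, train_fraction = 0.7, seed = 1,
                          class_col = "class") {
  stopifnot(is.data.frame(samples), class_col %in% names(samples))
  if (train_fraction <= 0 || train_fraction >= 1)
    abort("`train_fraction` must be in (0, 1)")
  cls <- as.character(samples[[class_col]])
  counts <- table(cls)
  small <- names(counts)[counts < 2L]
  if (length(small))
    abort("class '%s' has fewer than 2 samples", small[1])
  with_seed(seed, {
    tr_idx <- unlist(lapply(split(seq_len(nrow(samples)), cls),
                            function(id) {
      k <- round(train_fraction * length(id))
      k <- min(max(k, 1L), length(id) - 1L)
      sample(id, k)
    }), use.names = FALSE)
    list(train = samples[sort(tr_idx), , drop = FALSE],
         test = samples[setdiff(seq_len(nrow(samples)), tr_idx), ,
                        drop = FALSE])
  })
}

# coerce classifier input to a numeric matrix of feature vectors
as_feature_matrix <- function(x, feature_cols = NULL) {
  if (inherits(x, "canopy_raster"))
    return(do.call(cbind, lapply(x$bands, as.vector)))
  if (is.data.frame(x)) {
    if (!is.null(feature_cols)) x <- x[feature_cols]
    x <- x[vapply(x, is.numeric, logical(1))]
    return(as.matrix(x))
  }
  as.matrix(x)
}

#' Train a Gaussian maximum-likelihood classifier
#'
#' Estimates a mean vector and covariance per class from the training
#' samples.  Covariances are regularised by adding
#' `epsilon * trace / dim` to the diagonal, which keeps them positive
#' definite on small training sets; a warning notes classes with fewer
#' than `dim + 1` samples.  Priors default to equal (`"proportional"`
#' uses training frequencies).
#'
#' @param train training data frame (numeric features + class column).
#' @param class_col name of the class column.
#' @param priors `"equal"` or `"proportional"`.
#' @param epsilon covariance regularisation factor.
#' @return model of class `ml_model`.
#' @export
train_ml <- function(train, class_col = "class",
                     priors = c("equal", "proportional"),
                     epsilon = 1e-6) {
  stopifnot(is.data.frame(train), class_col %in% names(train))
  priors <- match.arg(priors)
  cls <- as.character(train[[class_col]])
  X <- as_feature_matrix(train[setdiff(names(train), class_col)])
  d <- ncol(X)
  classes <- sort(unique(cls))
  if (any(table(cls) < 2L))
    abort("every class needs >= 2 training samples")
  if (any(table(cls) < d + 1L))
    warning("some classes have fewer than dim+1 samples; ",
            "covariances are regularised")
  mods <- lapply(classes, function(cl) {
    Xi <- X[cls == cl, , drop = FALSE]
    mu <- colMeans(Xi)
    S <- cov(Xi)
    S <- S + diag(epsilon * sum(diag(S)) / d + 1e-10, d)
    list(mu = mu, sigma = S, inv = solve(S),
         logdet = determinant(S, logarithm = TRUE)$modulus[1])
  })
  names(mods) <- classes
  p <- if (priors == "equal") rep(1 / length(classes), length(classes))
       else as.numeric(table(factor(cls, classes)) / length(cls))
  structure(list(classes = classes, models = mods,
                 priors = setNames(p, classes),
                 features = colnames(X)), class = "ml_model")
}

#' Classify pixels with a maximum-likelihood model
#'
#' Evaluates the Gaussian discriminant
#' `g_c(x) = ln p(c) - 1/2 ln|S_c| - 1/2 (x - mu_c)' S_c^-1 (x - mu_c)`
#' and assigns each pixel to the class with the highest value.  With a
#' probability `threshold`, pixels whose smallest Mahalanobis term
#' exceeds the corresponding chi-square quantile (df = dimension) are
#' left unclassified — a dimension-independent way of expressing a
#' minimum-probability cutoff; without one every pixel is classified.
#'
#' @param x feature matrix (rows = pixels), data frame, or
#'   [canopy_raster] stack.
#' @param model an `ml_model` from [train_ml()].
#' @param threshold optional probability in (0, 1).
#' @return for raster input, a `classmap` [canopy_raster] (integer
#'   codes, 0 = unclassified, legend in attribute `"legend"`); otherwise
#'   a character vector of class names with `NA` for unclassified.
#' @export
classify_ml <- function(x, model, threshold = NULL) {
  stopifnot(inherits(model, "ml_model"))
  X <- as_feature_matrix(x, model$features)
  if (ncol(X) != length(model$models[[1]]$mu))
    abort("feature dimension mismatch: model has %d, input has %d",
          length(model$models[[1]]$mu), ncol(X))
  K <- length(model$classes)
  G <- matrix(-Inf, nrow(X), K)
  M <- matrix(Inf, nrow(X), K)
  for (k in seq_len(K)) {
    mod <- model$models[[k]]
    ctr <- sweep(X, 2, mod$mu)
    maha <- rowSums((ctr %*% mod$inv) * ctr)
    M[, k] <- maha
    G[, k] <- log(model$priors[k]) - 0.5 * mod$logdet - 0.5 * maha
  }
  win <- max.col(G, ties.method = "first")
  lab <- model$classes[win]
  if (!is.null(threshold)) {
    cut <- qchisq(threshold, df = ncol(X))
    lab[M[cbind(seq_len(nrow(X)), win)] > cut] <- NA_character_
  }
  finish_classmap(x, lab, model$classes)
}

finish_classmap <- function(x, lab, classes) {
  if (inherits(x, "canopy_raster")) {
    codes <- match(lab, classes)
    codes[is.na(codes)] <- 0L
    cm <- canopy_raster(matrix(codes, nrow(x$bands[[1]])),
                        x$cell_size_m, x$origin, role = "classmap",
                        band_names = "class")
    attr(cm, "legend") <- classes
    cm
  } else lab
}

#' Train a spectral-angle-mapper library
#'
#' The reference spectrum of each class is the mean (or median) of its
#' training feature vectors.
#'
#' @param train training data frame (numeric features + class column).
#' @param class_col name of the class column.
#' @param method `"mean"` (the class-mean vector) or `"median"`.
#' @return library of class `sam_library`.
#' @export
train_sam <- function(train, class_col = "class",
                      method = c("mean", "median")) {
  stopifnot(is.data.frame(train), class_col %in% names(train))
  method <- match.arg(method)
  cls <- as.character(train[[class_col]])
  X <- as_feature_matrix(train[setdiff(names(train), class_col)])
  classes <- sort(unique(cls))
  agg <- if (method == "mean") colMeans else
    function(m) apply(m, 2, median)
  spectra <- t(vapply(classes, function(cl)
    agg(X[cls == cl, , drop = FALSE]), numeric(ncol(X))))
  if (any(sqrt(rowSums(spectra^2)) < 1e-12))
    abort("a class reference spectrum is the zero vector")
  structure(list(classes = classes, spectra = spectra,
                 features = colnames(X)), class = "sam_library")
}

#' Classify pixels with the spectral angle mapper
#'
#' Computes the angle `acos(<x, r_c> / (|x| |r_c|))` between each pixel
#' vector and every class reference spectrum and assigns the class of
#' minimum angle.  Decisions are invariant to positive per-pixel
#' scaling (illumination).  Pixels whose minimum angle exceeds
#' `max_angle`, and zero pixel vectors (with a warning), are left
#' unclassified.
#'
#' @param x feature matrix, data frame, or [canopy_raster] stack.
#' @param library a `sam_library` from [train_sam()].
#' @param max_angle optional angle threshold in radians.
#' @return as [classify_ml()].
#' @export
classify_sam <- function(x, library, max_angle = NULL) {
  stopifnot(inherits(library, "sam_library"))
  X <- as_feature_matrix(x, library$features)
  if (ncol(X) != ncol(library$spectra))
    abort("feature dimension mismatch: library has %d, input has %d",
          ncol(library$spectra), ncol(X))
  nx <- sqrt(rowSums(X^2))
  nr <- sqrt(rowSums(library$spectra^2))
  cosang <- (X %*% t(library$spectra)) / outer(pmax(nx, 1e-300), nr)
  ang <- acos(pmin(pmax(cosang, -1), 1))
  win <- max.col(-ang, ties.method = "first")
  lab <- library$classes[win]
  zero <- nx < 1e-12
  if (any(zero)) {
    warning(sprintf("%d zero pixel vector(s) left unclassified",
                    sum(zero)))
    lab[zero] <- NA_character_
  }
  if (!is.null(max_angle))
    lab[ang[cbind(seq_along(win), win)] > max_angle] <- NA_character_
  finish_classmap(x, lab, library$classes)
}

#' Classification accuracy report
#'
#' Builds the confusion matrix (rows = reference, columns = predicted)
#' over the test samples and derives the standard accuracy battery:
#' overall accuracy (trace / total), Cohen's kappa
#' (`(p_o - p_e) / (1 - p_e)`, expectation from the marginals),
#' producer's accuracy (per-class recall, reference-conditioned) and
#' user's accuracy (per-class precision, prediction-conditioned; 0 is
#' reported for classes never predicted).  Unclassified predictions
#' (`NA`) count as errors in `overall_accuracy`;
#' `overall_accuracy_classified` excludes them from the denominator.
#'
#' @param predicted character vector of predicted classes (`NA` =
#'   unclassified), or a classmap raster plus test pixel indices.
#' @param reference character vector of reference classes.
#' @param classes optional class legend fixing the matrix order.
#' @return list of class `accuracy_report`: `confusion`,
#'   `overall_accuracy`, `overall_accuracy_classified`, `kappa`,
#'   `producers_accuracy`, `users_accuracy`, `n`.
#' @export
accuracy_report <- function(predicted, reference, classes = NULL) {
  predicted <- as.character(predicted)
  reference <- as.character(reference)
  if (!length(reference)) abort("empty test set")
  if (length(predicted) != length(reference))
    abort("predicted and reference lengths differ")
  if (is.null(classes)) classes <- sort(unique(reference))
  extra <- setdiff(reference, classes)
  if (length(extra))
    abort("reference label '%s' missing from the class legend", extra[1])
  has_uncl <- anyNA(predicted)
  pl <- c(classes, if (has_uncl) "unclassified")
  pred <- factor(ifelse(is.na(predicted), "unclassified", predicted),
                 levels = pl)
  ref <- factor(reference, levels = pl)
  cm <- table(reference = ref, predicted = pred)
  n <- sum(cm)
  diag_c <- diag(cm[classes, classes, drop = FALSE])
  oa <- sum(diag_c) / n
  classified <- !is.na(predicted)
  oa_cls <- if (any(classified))
    mean(predicted[classified] == reference[classified]) else NA_real_
  p_o <- sum(diag(cm)) / n
  p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else 0
  ref_tot <- rowSums(cm)[classes]
  pred_tot <- colSums(cm)[classes]
  producers <- ifelse(ref_tot > 0, diag_c / ref_tot, 0)
  users <- ifelse(pred_tot > 0, diag_c / pred_tot, 0)
  structure(list(confusion = cm, overall_accuracy = oa,
                 overall_accuracy_classified = oa_cls, kappa = kappa,
                 producers_accuracy = setNames(producers * 100, classes),
                 users_accuracy = setNames(users * 100, classes),
                 n = n), class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf(
    "<accuracy_report> n=%d  OA %.2f%%  kappa %.4f\n", x$n,
    100 * x$overall_accuracy, x$kappa))
  print(x$confusion)
  acc <- rbind(`Prod. Acc.%` = round(x$producers_accuracy, 1),
               `User Acc.%` = round(x$users_accuracy, 1))
  print(acc)
  invisible(x)
}

#' Spectral angles between pixels and library spectra
#'
#' The angle matrix underlying [classify_sam()]:
#' `acos(<x, r_c> / (|x| |r_c|))`, clipped to `[0, pi]`.
#'
#' @param x feature matrix (rows = pixels) or data frame.
#' @param library a `sam_library`.
#' @return matrix of angles in radians, one column per class.
#' @export
spectral_angles <- function(x, library) {
  stopifnot(inherits(library, "sam_library"))
  X <- as_feature_matrix(x, library$features)
  nx <- sqrt(rowSums(X^2))
  nr <- sqrt(rowSums(library$spectra^2))
  cosang <- (X %*% t(library$spectra)) / outer(pmax(nx, 1e-300), nr)
  ang <- acos(pmin(pmax(cosang, -1), 1))
  colnames(ang) <- library$classes
  ang
}
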