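#' Texture parameters
#'
#' @param window odd moving-window size in pixels (>= 3).  No single
#'   window size is canonical for crown-scale texture; the default of 7
#'   covers roughly a third of a small crown at the package's default
#'   0.5 m pixels and should be revisited for other resolutions.
#' @param levels number of grey levels (>= 2) for quantization
#'   (equal-width bins over the band's min-max range).
#' @param offsets integer matrix of `(drow, dcol)` co-occurrence
#'   offsets; default the four unit directions (0, 45, 90, 135 degrees).
#'   Pair counts are pooled over offsets into a single matrix.
#' @param symmetric count each pair in both directions (default TRUE).
#' @param features character vector from: first-order `"mean"`,
#'   `"variance"`, `"entropy1"`; co-occurrence `"contrast"`, `"ASM"`,
#'   `"entropy2"`, `"homogeneity"`, `"dissimilarity"`, `"correlation"`.
#' @return list of class `texture_params`.
#' @export
texture_params <- function(window = 7L, levels = 32L,
                           offsets = rbind(c(0L, 1L), c(1L, 0L),
                                           c(1L, 1L), c(1L, -1L)),
                           symmetric = TRUE,
                           features = c("mean", "variance", "entropy1",
                                        "contrast", "ASM", "entropy2")) {
  if (window < 3L || window %% 2L == 0L)
    abort("`window` must be odd and >= 3")
  if (levels < 2L) abort("`levels` must be >= 2")
  known <- c("mean", "variance", "entropy1", "contrast", "ASM",
             "entropy2", "homogeneity", "dissimilarity", "correlation")
  bad <- setdiff(features, known)
  if (length(bad)) abort("unknown texture feature '%s'", bad[1])
  structure(list(window = as.integer(window), levels = as.integer(levels),
                 offsets = offsets, symmetric = isTRUE(symmetric),
                 features = features), class = "texture_params")
}

# equal-width quantization of a band over [lo, hi] to 0..levels-1
quantize_band <- function(m, levels, rng = range(m, na.rm = TRUE)) {
  if (diff(rng) <= 0) return(matrix(0L, nrow(m), ncol(m)))
  q <- floor((m - rng[1]) / diff(rng) * levels)
  matrix(as.integer(pmin(pmax(q, 0), levels - 1)), nrow(m), ncol(m))
}

#' Grey-level co-occurrence matrix of one window
#'
#' Counts pairs of quantized grey levels at the given offsets within the
#' window (both directions when `symmetric`), pooled over offsets, and
#' normalises to sum 1.
#'
#' @param window_values numeric matrix of raw values.
#' @param params a [texture_params()] object.
#' @param rng quantization range; defaults to the window's own range
#'   (pass the full band range when the window is a crop of a band).
#' @return `levels x levels` matrix with non-negative entries summing
#'   to 1.
#' @export
glcm <- function(window_values, params = texture_params(),
                 rng = range(window_values)) {
  stopifnot(is.matrix(window_values))
  reach <- apply(abs(params$offsets), 2, max)
  if (nrow(window_values) <= reach[1] || ncol(window_values) <= reach[2])
    abort("window (%d x %d) smaller than the offset reach (%d, %d)",
          nrow(window_values), ncol(window_values), reach[1], reach[2])
  q <- quantize_band(window_values, params$levels, rng)
  L <- params$levels
  counts <- matrix(0, L, L)
  nr <- nrow(q); nc <- ncol(q)
  for (o in seq_len(nrow(params$offsets))) {
    dr <- params$offsets[o, 1]; dc <- params$offsets[o, 2]
    rs <- seq_len(nr); cs <- seq_len(nc)
    r1 <- rs[rs + dr >= 1 & rs + dr <= nr]
    c1 <- cs[cs + dc >= 1 & cs + dc <= nc]
    if (!length(r1) || !length(c1)) next
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + dr, c1 + dc, drop = FALSE]
    for (k in seq_along(a)) {
      counts[a[k] + 1L, b[k] + 1L] <- counts[a[k] + 1L, b[k] + 1L] + 1
      if (params$symmetric)
        counts[b[k] + 1L, a[k] + 1L] <- counts[b[k] + 1L, a[k] + 1L] + 1
    }
  }
  if (sum(counts) == 0) abort("no co-occurring pairs in window")
  counts / sum(counts)
}

#' Texture feature bands
#'
#' Computes the selected first-order and co-occurrence features in a
#' moving window around every pixel of the selected source bands
#' (mirrored padding at the edges).  First-order features come from the
#' raw window values / quantized histogram; co-occurrence features from
#' the pooled, normalised GLCM of the window.  All entropies are in
#' bits (log base 2).
#'
#' @param r an imagery [canopy_raster].
#' @param params a [texture_params()] object.
#' @param bands source band indices or names (default all).
#' @return a [canopy_raster] with role `"texture"`, one band per
#'   (source band x feature), named `<band>_<feature>`.
#' @export
texture_bands <- function(r, params = texture_params(),
                          bands = seq_len(n_bands(r))) {
  stopifnot(inherits(r, "canopy_raster"),
            inherits(params, "texture_params"))
  out <- list(); nm <- character()
  for (b in bands) {
    src <- r$bands[[b]]
    q <- quantize_band(src, params$levels)
    feats <- .texture_stack_cpp(src, q, params$window, params$levels,
                                params$offsets, params$symmetric,
                                params$features)
    for (f in seq_along(feats)) {
      out <- c(out, feats[f])
      nm <- c(nm, paste0(names(r$bands)[if (is.character(b))
        match(b, names(r$bands)) else b], "_", params$features[f]))
    }
  }
  canopy_raster(out, r$cell_size_m, r$origin, role = "texture",
                band_names = nm)
}

# Shannon entropy (bits) of a count/probability vector
entropy_bits <- function(p) {
  p <- p[p > 0]
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Rank features by gain ratio
#'
#' Discretises each continuous feature into equal-frequency bins and
#' scores it by gain ratio, the information gain about the class divided
#' by the feature's own split entropy:
#' `GR = (H(class) - H(class | feature)) / H(feature)`.  Constant
#' features (zero split information) get weight 0.  The ranking is
#' invariant under monotone rescaling of a feature (equal-frequency
#' bins) and lies in `[0, 1]`.
#'
#' @param samples data frame of numeric feature columns plus a class
#'   column.
#' @param bins number of equal-frequency bins.
#' @param class_col name of the class column.
#' @return data frame (`feature`, `gain_ratio`) sorted by descending
#'   weight, ties broken alphabetically.
#' @export
gain_ratio_rank <- function(samples, bins = 10L, class_col = "class") {
  stopifnot(is.data.frame(samples), class_col %in% names(samples))
  cls <- as.factor(samples[[class_col]])
  if (nlevels(droplevels(cls)) < 2L)
    abort("gain-ratio ranking needs at least 2 classes")
  feats <- setdiff(names(samples)[vapply(samples, is.numeric,
                                         logical(1))], class_col)
  if (!length(feats)) abort("no numeric feature columns")
  h_class <- entropy_bits(table(cls))
  gr <- vapply(feats, function(f) {
    x <- samples[[f]]
    br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1),
                          na.rm = TRUE))
    if (length(br) < 2L) return(0)     # constant feature
    d <- cut(x, br, include.lowest = TRUE)
    h_split <- entropy_bits(table(d))
    if (h_split <= 0) return(0)
    tab <- table(d, cls)
    n <- sum(tab)
    h_cond <- sum(vapply(seq_len(nrow(tab)), function(i) {
      w <- sum(tab[i, ]) / n
      if (w == 0) 0 else w * entropy_bits(tab[i, ])
    }, numeric(1)))
    max(0, (h_class - h_cond) / h_split)
  }, numeric(1))
  out <- data.frame(feature = feats, gain_ratio = unname(gr))
  out[order(-out$gain_ratio, out$feature), , drop = FALSE]
}
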